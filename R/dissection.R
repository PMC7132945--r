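# Virtual dissection: boolean SEED/AND/NOT gating of tractograms, slab ROI
# rasterization, bilateral seeding orchestration and transverse segment
# cutting between sagittal planes.

#' Region-of-interest specification
#'
#' An ROI is either an explicit binary mask or a declarative slab: one slice
#' (or mm offset) along an anatomical axis, spanning the whole section or a
#' restricted in-plane box, with optional carve-out boxes subtracted (the
#' whole-plane-except-the-temporal-lobes idiom).
#'
#' @param name ROI name.
#' @param role one of `"SEED"`, `"AND"`, `"NOT"`.
#' @param mask optional 3-D logical array (explicit geometry).
#' @param slab optional list describing a slab:
#'   `axis` (`"sagittal"` = x, `"coronal"` = y, `"axial"` = z),
#'   `slice` (0-based index) or `mm` (world offset along that axis),
#'   optional `extent` (list of `lo`/`hi` 0-based index bounds for the two
#'   in-plane axes; omitted = whole section), optional `carve_out` (list of
#'   boxes, each a 3 x 2 matrix of 0-based lo/hi index bounds, subtracted).
#' @param affine affine of the grid `mask` lives on (mask ROIs only).
#' @return A `roi_spec` object.
#' @export
roi_spec <- function(name, role, mask = NULL, slab = NULL, affine = NULL) {
  role <- match.arg(role, c("SEED", "AND", "NOT"))
  if (is.null(mask) == is.null(slab)) {
    stop("validation error: give exactly one of mask or slab", call. = FALSE)
  }
  if (!is.null(slab)) {
    slab$axis <- match.arg(slab$axis, c("sagittal", "coronal", "axial"))
    if (is.null(slab$slice) && is.null(slab$mm)) {
      stop("validation error: slab needs a slice index or mm offset",
           call. = FALSE)
    }
  }
  structure(list(name = name, role = role, mask = mask, slab = slab,
                 affine = affine), class = "roi_spec")
}

axis_index <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Rasterize an ROI specification to a binary mask
#'
#' @param spec a [roi_spec()].
#' @param grid_shape integer vector (nx, ny, nz).
#' @param affine voxel-to-world matrix of the target grid.
#' @return 3-D logical array.
#' @export
rasterize_roi <- function(spec, grid_shape, affine) {
  stopifnot(inherits(spec, "roi_spec"))
  if (!is.null(spec$mask)) {
    if (!all(dim(spec$mask) == grid_shape)) {
      stop("geometry error: mask ROI shape does not match grid", call. = FALSE)
    }
    return(array(as.logical(spec$mask), grid_shape))
  }
  slab <- spec$slab
  ax <- axis_index[[slab$axis]]
  if (!is.null(slab$slice)) {
    k <- as.integer(round(slab$slice))
  } else {
    # mm offset along the axis: nearest slice under the affine
    origin <- voxel_to_world(c(0, 0, 0), affine)
    spacing <- sqrt(sum(affine[1:3, ax]^2))
    k <- as.integer(round((slab$mm - origin[ax]) / spacing))
  }
  if (k < 0 || k >= grid_shape[ax]) {
    stop(sprintf("geometry error: ROI '%s' slab slice %d outside grid axis %d",
                 spec$name, k, ax), call. = FALSE)
  }
  m <- array(FALSE, grid_shape)
  idx <- list(seq_len(grid_shape[1]), seq_len(grid_shape[2]),
              seq_len(grid_shape[3]))
  idx[[ax]] <- k + 1L
  if (!is.null(slab$extent)) {
    in_plane <- setdiff(1:3, ax)
    for (j in seq_along(in_plane)) {
      a <- in_plane[j]
      lo <- max(0L, as.integer(slab$extent$lo[j]))
      hi <- min(grid_shape[a] - 1L, as.integer(slab$extent$hi[j]))
      idx[[a]] <- (lo:hi) + 1L
    }
  }
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  for (box in slab$carve_out %||% list()) {
    box <- matrix(as.integer(box), 3, 2)
    rng <- lapply(1:3, function(a) {
      (max(0L, box[a, 1]):min(grid_shape[a] - 1L, box[a, 2])) + 1L
    })
    m[rng[[1]], rng[[2]], rng[[3]]] <- FALSE
  }
  if (!any(m)) {
    stop(sprintf("validation error: ROI '%s' rasterizes to an empty mask",
                 spec$name), call. = FALSE)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gating protocol for one tract
#'
#' @param name protocol name.
#' @param seed a SEED [roi_spec()].
#' @param ands list of AND [roi_spec()]s (at least one for commissural
#'   protocols).
#' @param nots list of NOT [roi_spec()]s.
#' @param cut_planes numeric length-2: world-mm sagittal plane positions,
#'   strictly straddling the midline.
#' @param midline_mm world x of the midsagittal plane.
#' @param bilateral repeat tracking with SEED and first AND swapped.
#' @return A `gate_protocol` object.
#' @export
gate_protocol <- function(name, seed, ands, nots = list(),
                          cut_planes, midline_mm, bilateral = TRUE) {
  stopifnot(inherits(seed, "roi_spec"), seed$role == "SEED")
  for (r in ands) stopifnot(inherits(r, "roi_spec"), r$role == "AND")
  for (r in nots) stopifnot(inherits(r, "roi_spec"), r$role == "NOT")
  cut_planes <- sort(as.numeric(cut_planes))
  if (!(cut_planes[1] < midline_mm && cut_planes[2] > midline_mm)) {
    stop("validation error: cut planes must strictly straddle the midline",
         call. = FALSE)
  }
  structure(list(name = name, seed = seed, ands = ands, nots = nots,
                 cut_planes = cut_planes, midline_mm = midline_mm,
                 bilateral = bilateral),
            class = "gate_protocol")
}

#' @export
print.gate_protocol <- function(x, ...) {
  cat(sprintf(
    "<gate_protocol:%s> SEED %s | AND %s | NOT %s | cut planes %.2f / %.2f mm%s\n",
    x$name, x$seed$name,
    paste(vapply(x$ands, `[[`, "", "name"), collapse = ","),
    if (length(x$nots)) paste(vapply(x$nots, `[[`, "", "name"), collapse = ",") else "-",
    x$cut_planes[1], x$cut_planes[2],
    if (x$bilateral) " | bilateral" else ""))
  invisible(x)
}

# Voxel membership of every vertex of a streamline in a mask
# (nearest-voxel test; step sizes <= half a voxel keep missed crossings
# negligible -- documented limitation).
vertices_in_mask <- function(vertices, mask, affine) {
  ijk <- nearest_voxel(vertices, affine)
  inb <- voxel_in_bounds(ijk, dim(mask))
  hit <- logical(nrow(vertices))
  if (any(inb)) {
    lin <- 1 + ijk[inb, 1] + dim(mask)[1] * (ijk[inb, 2] + dim(mask)[2] * ijk[inb, 3])
    hit[inb] <- mask[lin]
  }
  hit
}

#' Filter a tractogram through AND/NOT gates
#'
#' A streamline survives iff it has at least one vertex in every AND mask
#' and no vertex in any NOT mask (NOT dominates). With
#' `and_mode = "terminate"`, only the two endpoints are tested against the
#' AND masks, mirroring engines that require termination inside the gate.
#'
#' @param t a [tractogram()].
#' @param protocol a [gate_protocol()], or a list with elements `ands` and
#'   `nots` holding [roi_spec()]s.
#' @param and_mode `"passage"` (default) or `"terminate"`.
#' @param verbose log survivor counts.
#' @return The gated [tractogram()] (order preserved; possibly empty).
#' @export
filter_by_gates <- function(t, protocol, and_mode = c("passage", "terminate"),
                            verbose = FALSE) {
  and_mode <- match.arg(and_mode)
  stopifnot(inherits(t, "tractogram"))
  affine <- t$space$affine
  shape <- NULL
  masks_of <- function(specs) lapply(specs, function(s) {
    if (!is.null(s$mask)) return(s$mask)
    stop("rasterize slab ROIs against the grid before gating (use ",
         "rasterize_roi and roi_spec(mask = ...))", call. = FALSE)
  })
  and_masks <- masks_of(protocol$ands)
  not_masks <- masks_of(protocol$nots)
  keep <- vapply(t$streamlines, function(s) {
    test_s <- if (and_mode == "terminate")
      s[c(1, nrow(s)), , drop = FALSE] else s
    for (m in and_masks) {
      if (!any(vertices_in_mask(test_s, m, affine))) return(FALSE)
    }
    for (m in not_masks) {
      if (any(vertices_in_mask(s, m, affine))) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- tractogram_allow(t$streamlines[keep], affine)
  if (verbose) {
    message(sprintf("gating: %d/%d streamlines survive",
                    length(out$streamlines), length(t$streamlines)))
  }
  out
}

#' Run a bilateral seeding protocol
#'
#' First pass seeds from the protocol's SEED ROI with the contralateral ROI
#' as the AND gate; the second pass swaps the two. Both passes share the
#' NOT gates.
#'
#' @param field an [orientation_field()].
#' @param protocol a bilateral [gate_protocol()] whose SEED and first AND
#'   carry explicit masks.
#' @param params a [tracking_params()].
#' @param and_mode AND-gate semantics, see [filter_by_gates()].
#' @return List with gated tractograms `left` and `right` (seeded from the
#'   SEED and swapped sides respectively), counts, and `failed` flag set
#'   when both passes are empty (reconstruction failure for the subject).
#' @export
run_bilateral_protocol <- function(field, protocol, params,
                                   and_mode = c("passage", "terminate")) {
  and_mode <- match.arg(and_mode)
  stopifnot(isTRUE(protocol$bilateral), length(protocol$ands) >= 1)
  seed_mask <- protocol$seed$mask
  contra <- protocol$ands[[1]]$mask
  if (is.null(seed_mask) || is.null(contra)) {
    stop("validation error: bilateral protocol needs explicit masks for ",
         "SEED and its contralateral AND", call. = FALSE)
  }
  one_pass <- function(smask, amask) {
    raw <- track_from_mask(field, smask, params)
    gates <- list(
      ands = c(list(roi_spec("contra", "AND", mask = amask)),
               protocol$ands[-1]),
      nots = protocol$nots)
    filter_by_gates(raw, gates, and_mode = and_mode)
  }
  left <- one_pass(seed_mask, contra)
  right <- one_pass(contra, seed_mask)
  failed <- length(left$streamlines) == 0 && length(right$streamlines) == 0
  if (failed) {
    warning(sprintf("protocol '%s': reconstruction failed (both passes empty)",
                    protocol$name), call. = FALSE)
  }
  structure(list(left = left, right = right, failed = failed,
                 protocol = protocol$name),
            class = "bilateral_reconstruction")
}

#' Cut a transverse segment between two sagittal planes
#'
#' For each streamline every maximal contiguous vertex run lying strictly
#' between the planes is retained; streamlines with no such run contribute
#' nothing. Vertices are never resampled, so segment vertices are a subset
#' of the input vertices.
#'
#' @param t a [tractogram()].
#' @param cut_planes numeric length-2, world-mm x positions of the sagittal
#'   planes.
#' @param provenance `"L2R"` or `"R2L"` tag recording the seeding side.
#' @return A `tract_segment`: list of vertex-run matrices, total vertex
#'   count `n`, and the provenance tag.
#' @export
cut_segment <- function(t, cut_planes, provenance = "L2R") {
  cp <- as.numeric(cut_planes)
  if (length(cp) != 2 || cp[1] >= cp[2]) {
    stop("validation error: cut planes must be two increasing positions",
         call. = FALSE)
  }
  runs <- list()
  for (s in t$streamlines) {
    inside <- s[, 1] > cp[1] & s[, 1] < cp[2]
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      runs[[length(runs) + 1]] <- s[starts[j]:ends[j], , drop = FALSE]
    }
  }
  structure(list(runs = runs,
                 n = sum(vapply(runs, nrow, 1L)),
                 provenance = provenance,
                 cut_planes = cp,
                 affine = t$space$affine),
            class = "tract_segment")
}

#' @export
print.tract_segment <- function(x, ...) {
  cat(sprintf("<tract_segment:%s> %d runs, N = %d vertices between x = %.2f and %.2f mm\n",
              x$provenance, length(x$runs), x$n, x$cut_planes[1],
              x$cut_planes[2]))
  invisible(x)
}
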