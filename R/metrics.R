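# Tractometry: sample scalar maps at segment vertices and combine the
# left-/right-seeded segment means with vertex-count weights.

#' Sample a scalar map along a tract segment
#'
#' One value per retained vertex, by trilinear interpolation of the map at
#' the vertex's world position (nearest-neighbour available for
#' sensitivity checks).
#'
#' @param segment a `tract_segment` from [cut_segment()].
#' @param map a [scalar_map()].
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return Numeric vector of per-vertex values (length `segment$n`).
#' @export
sample_scalar_along <- function(segment, map,
                                method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(segment, "tract_segment"), inherits(map, "scalar_map"))
  if (segment$n == 0) return(numeric(0))
  pts <- do.call(rbind, segment$runs)
  interp_scalar(map, pts, method)
}

interp_scalar <- function(map, pts, method = "trilinear") {
  dims <- dim(map$values)
  ijk <- world_to_voxel(pts, map$affine)
  if (method == "nearest") {
    r <- round(ijk)
    if (any(!voxel_in_bounds(r, dims))) {
      bad <- which(!voxel_in_bounds(r, dims))[1]
      stop(sprintf("vertex %d at (%.2f, %.2f, %.2f) mm outside map extent",
                   bad, pts[bad, 1], pts[bad, 2], pts[bad, 3]), call. = FALSE)
    }
    return(map$values[1 + r[, 1] + dims[1] * (r[, 2] + dims[2] * r[, 3])])
  }
  f <- floor(ijk)
  w <- ijk - f
  # clamp so border vertices interpolate within the outermost cell
  f <- pmin(pmax(f, 0), matrix(rep(dims - 2, each = nrow(f)), ncol = 3))
  w <- ijk - f
  if (any(w < -1e-9) || any(w > 1 + 1e-9)) {
    bad <- which(rowSums(w < -1e-9 | w > 1 + 1e-9) > 0)[1]
    stop(sprintf("vertex %d at (%.2f, %.2f, %.2f) mm outside map extent",
                 bad, pts[bad, 1], pts[bad, 2], pts[bad, 3]), call. = FALSE)
  }
  w <- pmin(pmax(w, 0), 1)
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    lin <- 1 + (f[, 1] + dx) + dims[1] * ((f[, 2] + dy) + dims[2] * (f[, 3] + dz))
    acc <- acc + wt * map$values[lin]
  }
  acc
}

#' Vertex-weighted mean of two per-side segment means
#'
#' The combination rule for left- and right-seeded transverse segments:
#' (N_L * mean_L + N_R * mean_R) / (N_L + N_R), applied once for FA and
#' once for MD. Weighting by vertex count absorbs differences in how many
#' streamlines each seeding direction contributed.
#'
#' @param n_l,n_r vertex counts of the left-/right-seeded segments.
#' @param mean_l,mean_r per-side mean scalar values.
#' @return The vertex-weighted mean.
#' @export
vertex_weighted_mean <- function(n_l, mean_l, n_r, mean_r) {
  stopifnot(n_l >= 0, n_r >= 0)
  if (n_l + n_r == 0) {
    stop("undefined metric: both segments have zero vertices", call. = FALSE)
  }
  if (n_l == 0) return(mean_r)
  if (n_r == 0) return(mean_l)
  (n_l * mean_l + n_r * mean_r) / (n_l + n_r)
}

#' Tractometry summary of a left/right segment pair
#'
#' Per-side means pool all retained vertices of that side (vertices, not
#' streamlines, are the unit, matching the combination formulas); combined
#' values use [vertex_weighted_mean()].
#'
#' @param seg_l,seg_r `tract_segment`s for the left- and right-seeded
#'   reconstructions.
#' @param fa,md [scalar_map()]s.
#' @param method interpolation passed to [sample_scalar_along()].
#' @param subject,tract optional identifiers carried into the output.
#' @return A one-row tibble: `subject`, `tract`, `n_l`, `n_r`, `fa_l`,
#'   `fa_r`, `md_l`, `md_r`, `fa_vw`, `md_vw`.
#' @export
segment_metrics <- function(seg_l, seg_r, fa, md, method = "trilinear",
                            subject = NA_character_, tract = NA_character_) {
  n_l <- seg_l$n; n_r <- seg_r$n
  if (n_l + n_r == 0) {
    stop("undefined metric: both segments empty; subject should be flagged ",
         "and excluded downstream", call. = FALSE)
  }
  side <- function(seg, map) {
    if (seg$n == 0) return(NA_real_)
    mean(sample_scalar_along(seg, map, method))
  }
  fa_l <- side(seg_l, fa); fa_r <- side(seg_r, fa)
  md_l <- side(seg_l, md); md_r <- side(seg_r, md)
  vw <- function(a, b) {
    vertex_weighted_mean(n_l, ifelse(is.na(a), 0, a),
                         n_r, ifelse(is.na(b), 0, b))
  }
  tibble::tibble(
    subject = subject, tract = tract,
    n_l = n_l, n_r = n_r,
    fa_l = fa_l, fa_r = fa_r, md_l = md_l, md_r = md_r,
    fa_vw = vw(fa_l, fa_r), md_vw = vw(md_l, md_r))
}

#' Dissect one tract and measure it, end to end
#'
#' Convenience wrapper: bilateral gated tracking, transverse segment
#' cutting at the protocol's sagittal planes, and vertex-weighted
#' tractometry.
#'
#' @param field an [orientation_field()].
#' @param protocol a [gate_protocol()].
#' @param params a [tracking_params()].
#' @param fa,md [scalar_map()]s to sample.
#' @param ... passed to [segment_metrics()].
#' @return A one-row tibble as in [segment_metrics()], or `NULL` when the
#'   reconstruction failed in both directions.
#' @export
dissect_and_measure <- function(field, protocol, params, fa, md, ...) {
  rec <- run_bilateral_protocol(field, protocol, params)
  if (rec$failed) return(NULL)
  seg_l <- cut_segment(rec$left, protocol$cut_planes, "L2R")
  seg_r <- cut_segment(rec$right, protocol$cut_planes, "R2L")
  if (seg_l$n + seg_r$n == 0) return(NULL)
  segment_metrics(seg_l, seg_r, fa, md, tract = protocol$name, ...)
}
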