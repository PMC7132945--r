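# Deterministic streamline propagation over a per-voxel peak field.
#
# The tracker is intentionally free of randomness: repeated runs over the
# same field and parameters are bit-identical. Peaks are looked up at the
# nearest voxel (no interpolation of multi-peak sets), integration is
# Euler at a fixed step, and the turning angle is measured per step.

#' Orientation field: per-voxel unit peak directions with amplitudes
#'
#' @param peaks 5-D array (nx, ny, nz, K, 3) of peak directions; slots with
#'   zero amplitude are ignored.
#' @param amplitudes 4-D array (nx, ny, nz, K) of nonnegative amplitudes.
#' @param affine voxel-to-world matrix.
#' @param support optional 3-D logical array; defaults to voxels with any
#'   positive amplitude.
#' @return An `orientation_field` object.
#' @export
orientation_field <- function(peaks, amplitudes, affine, support = NULL) {
  stopifnot(length(dim(peaks)) == 5, dim(peaks)[5] == 3,
            all(dim(amplitudes) == dim(peaks)[1:4]))
  if (any(amplitudes < 0)) {
    stop("validation error: negative peak amplitude", call. = FALSE)
  }
  dimp <- dim(peaks)
  nvox <- prod(dimp[1:3]); K <- dimp[4]
  pm <- matrix(peaks, nvox * K, 3)
  am <- as.vector(amplitudes)
  act <- am > 0
  if (any(act)) {
    nrm <- sqrt(rowSums(pm[act, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("validation error: active peak directions must be unit-norm",
           call. = FALSE)
    }
  }
  if (is.null(support)) {
    support <- array(rowSums(matrix(act, nvox, K)) > 0, dimp[1:3])
  }
  structure(list(peaks = peaks, amplitudes = amplitudes, affine = affine,
                 support = support), class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s grid, K = %d peak slots, %d support voxels\n",
              paste(dim(x$support), collapse = " x "), dim(x$peaks)[4],
              sum(x$support)))
  invisible(x)
}

#' Tracking parameters
#'
#' Defaults follow the human protocol: 0.5 mm steps (use 0.1 mm for
#' ex vivo data), 60 degree angle threshold, 4x4x4 supersampled seeding
#' (64 streamline initiation points per seed voxel).
#'
#' @param step_size_mm Euler step length.
#' @param angle_threshold_deg maximum per-step turning angle.
#' @param supersample_per_axis k: seeds at the k^3 uniform subgrid of each
#'   seed voxel.
#' @param max_length_mm total streamline length budget (both arms).
#' @param min_vertices reject streamlines with fewer vertices.
#' @return A `tracking_params` object.
#' @export
tracking_params <- function(step_size_mm = 0.5, angle_threshold_deg = 60,
                            supersample_per_axis = 4L, max_length_mm = 250,
                            min_vertices = 3L) {
  stopifnot(step_size_mm > 0,
            angle_threshold_deg > 0, angle_threshold_deg < 180,
            supersample_per_axis >= 1,
            max_length_mm > step_size_mm,
            min_vertices >= 2)
  structure(list(step_size_mm = step_size_mm,
                 angle_threshold_deg = angle_threshold_deg,
                 supersample_per_axis = as.integer(supersample_per_axis),
                 max_length_mm = max_length_mm,
                 min_vertices = as.integer(min_vertices)),
            class = "tracking_params")
}

#' Supersampled seed points for a mask
#'
#' Each seed voxel contributes the centers of its k x k x k uniform
#' subdivision (k = 4 gives the protocol's 64 initiation points per voxel),
#' converted to world mm. Ordering is deterministic: voxels in column-major
#' grid order, subgrid points x-fastest within each voxel.
#'
#' @param seed_mask 3-D logical array.
#' @param affine voxel-to-world matrix.
#' @param k supersampling factor per axis.
#' @return n x 3 matrix of world-mm seed points (0 rows, with a warning,
#'   for an empty mask).
#' @export
seed_points <- function(seed_mask, affine, k = 4L) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  vox <- which(seed_mask)
  if (!length(vox)) {
    warning("empty seed mask: no seed points", call. = FALSE)
    return(matrix(numeric(0), 0, 3))
  }
  dims <- dim(seed_mask)
  v0 <- vox - 1L
  i <- v0 %% dims[1]
  j <- (v0 %/% dims[1]) %% dims[2]
  l <- v0 %/% (dims[1] * dims[2])
  # subgrid offsets in voxel units, centered: (-1/2, 1/2) split into k cells
  off1 <- (2 * seq_len(k) - 1) / (2 * k) - 0.5
  sub <- as.matrix(expand.grid(x = off1, y = off1, z = off1))  # x fastest
  nv <- length(vox); ns <- nrow(sub)
  ijk <- cbind(rep(i, each = ns) + rep(sub[, 1], nv),
               rep(j, each = ns) + rep(sub[, 2], nv),
               rep(l, each = ns) + rep(sub[, 3], nv))
  voxel_to_world(ijk, affine)
}

#' Propagate one streamline bidirectionally
#'
#' From the start point the largest-amplitude peak of the nearest voxel
#' gives the first arm's initial direction; the second arm starts with its
#' negation. Each Euler step moves `step_size_mm` along the resident peak
#' (or its negation) that minimises the turning angle from the incoming
#' direction; an arm ends when it leaves the support, the turning angle
#' exceeds the threshold, or the combined length would exceed
#' `max_length_mm`. The two arms are concatenated sharing the start vertex.
#'
#' @param field an [orientation_field()].
#' @param start length-3 world-mm point.
#' @param params a [tracking_params()].
#' @return n x 3 vertex matrix, or a `tracking_rejection` object with a
#'   `reason` field (`"out_of_support"` or `"too_short"`).
#' @export
propagate_streamline <- function(field, start, params) {
  ctx <- tracker_context(field, params)
  propagate_one(ctx, as.numeric(start))
}

rejection <- function(reason) {
  structure(list(reason = reason), class = "tracking_rejection")
}

# Precomputed arrays for the inner loop (shared across seeds).
tracker_context <- function(field, params) {
  dimp <- dim(field$peaks)
  nvox <- prod(dimp[1:3]); K <- dimp[4]
  list(
    pk = matrix(field$peaks, nvox * K, 3),
    am = matrix(field$amplitudes, nvox, K),
    support = as.vector(field$support),
    dims = dimp[1:3],
    nvox = nvox, K = K,
    inv = solve_affine(field$affine)[1:3, , drop = FALSE],
    step = params$step_size_mm,
    cos_thresh = cos(params$angle_threshold_deg * pi / 180),
    max_steps_total = floor(params$max_length_mm / params$step_size_mm),
    min_vertices = params$min_vertices
  )
}

# 1-based linear voxel index of a world point, or NA outside grid.
.lin_voxel <- function(ctx, p) {
  q <- ctx$inv %*% c(p, 1)
  i <- round(q[1]); j <- round(q[2]); l <- round(q[3])
  if (i < 0 || j < 0 || l < 0 ||
      i >= ctx$dims[1] || j >= ctx$dims[2] || l >= ctx$dims[3]) return(NA_integer_)
  as.integer(1 + i + ctx$dims[1] * (j + ctx$dims[2] * l))
}

propagate_one <- function(ctx, start) {
  v0 <- .lin_voxel(ctx, start)
  if (is.na(v0) || !ctx$support[v0]) {
    return(rejection("out_of_support"))
  }
  a0 <- ctx$am[v0, ]
  k0 <- which.max(a0)
  d0 <- ctx$pk[v0 + (k0 - 1L) * ctx$nvox, ]

  arm <- function(d, budget) {
    # returns matrix of vertices beyond the start (possibly 0 rows)
    if (budget <= 0L) return(matrix(numeric(0), 0, 3))
    verts <- matrix(NA_real_, budget, 3)
    n <- 0L
    p <- start
    while (n < budget) {
      v <- .lin_voxel(ctx, p)
      amp <- ctx$am[v, ]
      best_dot <- -2; best_dir <- NULL
      for (kk in seq_len(ctx$K)) {
        if (amp[kk] <= 0) next
        q <- ctx$pk[v + (kk - 1L) * ctx$nvox, ]
        dt <- q[1] * d[1] + q[2] * d[2] + q[3] * d[3]
        s <- if (dt < 0) -1 else 1
        if (s * dt > best_dot) { best_dot <- s * dt; best_dir <- s * q }
      }
      # terminate on angle violation or (degenerate) peakless support voxel
      if (is.null(best_dir) || best_dot < ctx$cos_thresh) break
      p_new <- p + ctx$step * best_dir
      v_new <- .lin_voxel(ctx, p_new)
      if (is.na(v_new) || !ctx$support[v_new]) break  # exits support
      p <- p_new
      d <- best_dir
      n <- n + 1L
      verts[n, ] <- p
    }
    verts[seq_len(n), , drop = FALSE]
  }

  arm1 <- arm(d0, ctx$max_steps_total)
  arm2 <- arm(-d0, max(0L, ctx$max_steps_total - nrow(arm1)))
  verts <- rbind(arm1[rev(seq_len(nrow(arm1))), , drop = FALSE],
                 matrix(start, 1, 3),
                 arm2)
  if (nrow(verts) < ctx$min_vertices) {
    return(rejection("too_short"))
  }
  verts
}

#' Track from every supersampled seed of a mask
#'
#' Applies [propagate_streamline()] to each seed point of
#' [seed_points()]; output order follows seed order, so runs are fully
#' deterministic.
#'
#' @param field an [orientation_field()].
#' @param seed_mask 3-D logical array in the field's grid.
#' @param params a [tracking_params()].
#' @param verbose log counts in/out at INFO level.
#' @return A [tractogram()] (possibly empty, with a warning); attribute
#'   `rejections` holds the per-reason rejection counts.
#' @export
track_from_mask <- function(field, seed_mask, params, verbose = FALSE) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(params, "tracking_params"))
  seeds <- seed_points(seed_mask, field$affine, params$supersample_per_axis)
  ctx <- tracker_context(field, params)
  out <- vector("list", nrow(seeds))
  n_keep <- 0L
  rej <- c(out_of_support = 0L, too_short = 0L)
  for (s in seq_len(nrow(seeds))) {
    sl <- propagate_one(ctx, seeds[s, ])
    if (inherits(sl, "tracking_rejection")) {
      rej[sl$reason] <- rej[sl$reason] + 1L
    } else {
      n_keep <- n_keep + 1L
      out[[n_keep]] <- sl
    }
  }
  if (verbose) {
    message(sprintf("tracking: %d seeds -> %d streamlines (%s)",
                    nrow(seeds), n_keep,
                    paste(names(rej), rej, sep = "=", collapse = ", ")))
  }
  if (n_keep == 0L) {
    warning("tracking produced no streamlines", call. = FALSE)
  }
  t <- tractogram_allow(out[seq_len(n_keep)], field$affine)
  attr(t, "rejections") <- rej
  t
}
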