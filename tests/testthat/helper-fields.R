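# Hand-built orientation fields and tiny fixtures shared across tests.

# A straight single-peak corridor along +x: nx voxels long, 3 x 3 in
# cross-section, surrounded by empty (non-support) space.
corridor_field <- function(nx = 20, voxel = 1) {
  dims <- c(nx + 4, 7, 7)
  peaks <- array(0, c(dims, 1, 3))
  amps <- array(0, c(dims, 1))
  xs <- 3:(nx + 2); ys <- 3:5; zs <- 3:5
  peaks[xs, ys, zs, 1, 1] <- 1
  amps[xs, ys, zs, 1] <- 0.8
  orientation_field(peaks, amps, diag_affine_t(voxel))
}

# An elbow: corridor along +x that turns 90 degrees into +y.
elbow_field <- function(arm = 10, voxel = 1) {
  dims <- c(arm + 4, arm + 4, 5)
  peaks <- array(0, c(dims, 1, 3))
  amps <- array(0, c(dims, 1))
  # x-limb at y = 3, z = 3 (1-based grid rows 3..arm+2)
  peaks[3:(arm + 2), 3, 3, 1, 1] <- 1
  amps[3:(arm + 2), 3, 3, 1] <- 0.8
  # y-limb rising from the elbow voxel
  peaks[arm + 2, 4:(arm + 2), 3, 1, 2] <- 1
  amps[arm + 2, 4:(arm + 2), 3, 1] <- 0.8
  orientation_field(peaks, amps, diag_affine_t(voxel))
}

diag_affine_t <- function(v) diag(c(v, v, v, 1))

# One-voxel mask helper (0-based index).
one_voxel_mask <- function(dims, ijk0) {
  m <- array(FALSE, dims)
  m[ijk0[1] + 1, ijk0[2] + 1, ijk0[3] + 1] <- TRUE
  m
}

# Straight-line streamline helper.
line_streamline <- function(from, to, n = 10) {
  tt <- seq(0, 1, length.out = n)
  cbind(from[1] + tt * (to[1] - from[1]),
        from[2] + tt * (to[2] - from[2]),
        from[3] + tt * (to[3] - from[3]))
}

# Small shared phantom, built once per test run.
shared_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom("dhc_default")
    cache
  }
})

# Turning angles (degrees) at the interior vertices of a streamline.
turning_angles <- function(s) {
  if (nrow(s) < 3) return(numeric(0))
  d <- diff(s)
  d <- d / sqrt(rowSums(d^2))
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  acos(pmin(pmax(dots, -1), 1)) * 180 / pi
}
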