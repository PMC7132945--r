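# Shared geometric conventions.
#
# Voxel indices are 0-based throughout, and index i names the CENTER of
# voxel i under the affine (NIfTI convention): world = A %*% c(i, j, k, 1).
# All streamline vertices live in world mm; per-file conventions (TRK
# voxel-corner offsets) are normalised at the I/O boundary.

#' Convert 0-based voxel indices to world coordinates
#'
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional), or a length-3 vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world-mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind_point(ijk)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  xyz <- cbind(ijk, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Convert world coordinates to 0-based (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world-mm points, or a length-3 vector.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- rbind_point(xyz)
  inv <- solve_affine(affine)
  ijk <- cbind(xyz, 1) %*% t(inv)
  ijk[, 1:3, drop = FALSE]
}

rbind_point <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = ncol(x), dimnames = NULL)
}

solve_affine <- function(affine) {
  inv <- try(solve(affine), silent = TRUE)
  if (inherits(inv, "try-error")) {
    stop("geometry error: affine is not invertible", call. = FALSE)
  }
  inv
}

# Nearest-voxel lookup: world point -> 0-based integer indices (rounded).
nearest_voxel <- function(xyz, affine) {
  round(world_to_voxel(xyz, affine))
}

# TRUE for each row of 0-based integer ijk that lies inside `dim`.
voxel_in_bounds <- function(ijk, dim3) {
  ijk[, 1] >= 0 & ijk[, 1] < dim3[1] &
    ijk[, 2] >= 0 & ijk[, 2] < dim3[2] &
    ijk[, 3] >= 0 & ijk[, 3] < dim3[3]
}

# Simple scaled-identity affine: world = index * voxel_size (0-based centers).
diag_affine <- function(voxel_size) {
  a <- diag(c(rep(voxel_size, length.out = 3), 1))
  a
}
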