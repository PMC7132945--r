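# Diffusion tensor fitting (log-linear least squares) and the scalar maps
# derived from it. The principal-eigenvector field doubles as the tracker's
# single-peak orientation field.

#' Fit the diffusion tensor by linear least squares
#'
#' Ordinary least squares of log(S) against the six unique tensor elements
#' plus an intercept (log S0), per voxel inside the brain mask. Nonpositive
#' signals are floored at a machine-epsilon-scaled positive value before
#' the log. For multishell human data the default shell predicate keeps
#' b <= 1000 s/mm^2 only, so tensor maps derive from the b = 1000 shell;
#' b-values below 50 count as b = 0.
#'
#' @param d a [dwi_dataset()].
#' @param shell_selection predicate on b-values choosing the volumes used;
#'   default keeps `b <= 1000`.
#' @return A `tensor_field`: per-voxel tensor coefficient array
#'   (nx, ny, nz, 6; order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `log_s0`,
#'   eigenvalues (descending) and principal eigenvectors, a `fail` flag
#'   array for voxels whose fit is unusable (flagged, not zeroed), and the
#'   mask/affine.
#' @export
fit_tensor_lls <- function(d, shell_selection = function(b) b <= 1000) {
  stopifnot(inherits(d, "dwi_dataset"))
  use <- which(shell_selection(d$gradients$bvals))
  b <- d$gradients$bvals[use]
  g <- d$gradients$bvecs[use, , drop = FALSE]
  n_b0 <- sum(b < 50)
  n_dw <- sum(b >= 50)
  if (length(use) < 7 || n_b0 < 1 || n_dw < 6) {
    stop(sprintf(paste0("insufficient data: need >= 1 b0 and >= 6 ",
                        "diffusion-weighted volumes, got %d + %d"),
                 n_b0, n_dw), call. = FALSE)
  }
  # design: log S = log S0 - b (g' D g), 6 unique elements of D
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7) {
    kappa_est <- kappa(X)
    stop(sprintf(
      "geometry error: singular tensor design matrix (condition number %.3g); directions are not independent",
      kappa_est), call. = FALSE)
  }
  dims <- dim(d$signal)[1:3]
  vox <- which(d$brain_mask)
  nvol <- length(use)
  sig <- matrix(aperm(d$signal[, , , use, drop = FALSE], c(4, 1, 2, 3)),
                nvol)[, vox, drop = FALSE]
  floor_val <- .Machine$double.eps * max(sig, 1)
  sig[sig <= 0] <- floor_val
  beta <- qr.coef(qrX, log(sig))          # 7 x nvox
  coefs <- array(0, c(dims, 6))
  log_s0 <- array(NA_real_, dims)
  log_s0[vox] <- beta[1, ]
  for (q in 1:6) {
    page <- array(0, dims)
    page[vox] <- beta[q + 1, ]
    coefs[, , , q] <- page
  }
  ev <- eigen_sym3(t(beta[2:7, , drop = FALSE]))
  evals <- array(NA_real_, c(dims, 3))
  evecs <- array(NA_real_, c(dims, 3))
  for (q in 1:3) {
    page <- array(NA_real_, dims); page[vox] <- ev$values[, q]
    evals[, , , q] <- page
    page <- array(NA_real_, dims); page[vox] <- ev$vector1[, q]
    evecs[, , , q] <- page
  }
  fail <- array(FALSE, dims)
  fail[vox] <- !is.finite(ev$values[, 1]) | !is.finite(beta[1, ])
  structure(list(coefs = coefs, log_s0 = log_s0, evals = evals,
                 evec1 = evecs, fail = fail, mask = d$brain_mask,
                 affine = d$affine),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s grid, %d fitted voxels (%d flagged)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              sum(x$fail)))
  invisible(x)
}

# Vectorised eigen decomposition of symmetric 3x3 matrices.
# `m6`: n x 6 matrix (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz). Returns descending
# eigenvalues (n x 3) and the principal eigenvector (n x 3, unit norm).
# Trigonometric method for the eigenvalues; the principal eigenvector is a
# maximal column of (D - l2 I)(D - l3 I), which spans the l1 eigenspace.
eigen_sym3 <- function(m6) {
  a <- m6[, 1]; b <- m6[, 2]; c <- m6[, 3]
  d <- m6[, 4]; e <- m6[, 5]; f <- m6[, 6]
  tr <- a + b + c
  q <- tr / 3
  a_ <- a - q; b_ <- b - q; c_ <- c - q
  p2 <- (a_^2 + b_^2 + c_^2) / 6 + (d^2 + e^2 + f^2) / 3
  p <- sqrt(pmax(p2, 0))
  # det of (D - qI)/p
  detB <- ifelse(p > 0,
                 (a_ * (b_ * c_ - f^2) - d * (d * c_ - f * e) +
                    e * (d * f - b_ * e)) / p^3,
                 0)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- tr - l1 - l3
  n <- length(a)
  # principal eigenvector via C = (D - l2 I)(D - l3 I); any nonzero column
  # of C is an eigenvector for l1. Choose the largest per voxel.
  v <- matrix(NA_real_, n, 3)
  A11 <- a - l2; A22 <- b - l2; A33 <- c - l2
  B11 <- a - l3; B22 <- b - l3; B33 <- c - l3
  cols <- list(
    cbind(A11 * B11 + d * d + e * e,
          d * B11 + A22 * d + f * e,
          e * B11 + f * d + A33 * e),
    cbind(A11 * d + d * B22 + e * f,
          d * d + A22 * B22 + f * f,
          e * d + f * B22 + A33 * f),
    cbind(A11 * e + d * f + e * B33,
          d * e + A22 * f + f * B33,
          e * e + f * f + A33 * B33))
  nrm <- vapply(cols, function(cc) rowSums(cc^2), numeric(n))
  nrm <- matrix(nrm, n, 3)
  pick <- max.col(nrm, ties.method = "first")
  for (j in 1:3) {
    sel <- pick == j & nrm[, j] > 0
    if (any(sel)) {
      cc <- cols[[j]][sel, , drop = FALSE]
      v[sel, ] <- cc / sqrt(rowSums(cc^2))
    }
  }
  # degenerate (isotropic) voxels: eigenvector arbitrary; use +x
  deg <- !is.finite(v[, 1]) | (nrm[cbind(seq_len(n), pick)] == 0)
  v[deg, ] <- rep(c(1, 0, 0), each = sum(deg))
  list(values = cbind(l1, l2, l3), vector1 = v)
}

# FA from descending eigenvalues (Basser-Pierpaoli closed form).
fa_from_evals <- function(l1, l2, l3) {
  md <- (l1 + l2 + l3) / 3
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.xmin))
  fa[den == 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Compute FA and MD scalar maps from a fitted tensor field
#'
#' MD is the eigenvalue mean; FA the usual normalised eigenvalue dispersion
#' sqrt(3/2) * ||lambda - MD|| / ||lambda||, clipped to \[0, 1\]. Negative
#' eigenvalues are clamped to zero for FA only and the voxel flagged.
#'
#' @param t a `tensor_field` from [fit_tensor_lls()].
#' @return List with `fa` and `md` [scalar_map()]s; `attr(, "neg_flag")`
#'   marks voxels with clamped negative eigenvalues.
#' @export
compute_fa_md <- function(t) {
  stopifnot(inherits(t, "tensor_field"))
  l1 <- t$evals[, , , 1]; l2 <- t$evals[, , , 2]; l3 <- t$evals[, , , 3]
  md <- (l1 + l2 + l3) / 3
  neg <- (l1 < 0 | l2 < 0 | l3 < 0) & t$mask
  fa <- fa_from_evals(pmax(l1, 0), pmax(l2, 0), pmax(l3, 0))
  md[!t$mask] <- 0
  fa[!t$mask] <- 0
  fa[is.na(fa)] <- 0
  md[is.na(md)] <- 0
  out <- list(fa = scalar_map(fa, t$affine, "FA"),
              md = scalar_map(md, t$affine, "MD"))
  attr(out, "neg_flag") <- neg
  out
}

#' Single-peak orientation field from a tensor field
#'
#' One peak per voxel: the principal eigenvector, with FA as amplitude;
#' support restricted to voxels with FA at or above `fa_floor`.
#'
#' @param t a `tensor_field`.
#' @param fa_floor FA support threshold (0 makes support = brain mask).
#' @return An [orientation_field()] with K = 1.
#' @export
derive_peak_field <- function(t, fa_floor = 0.1) {
  stopifnot(inherits(t, "tensor_field"), fa_floor >= 0, fa_floor <= 1)
  maps <- compute_fa_md(t)
  fa <- maps$fa$values
  dims <- dim(t$mask)
  support <- t$mask & (fa >= fa_floor) & !t$fail
  peaks <- array(0, c(dims, 1, 3))
  amps <- array(0, c(dims, 1))
  for (q in 1:3) {
    page <- t$evec1[, , , q]
    page[!support | !is.finite(page)] <- if (q == 1) 1 else 0
    peaks[, , , 1, q] <- page
  }
  amps[, , , 1] <- ifelse(support, pmax(fa, .Machine$double.eps), 0)
  orientation_field(peaks, amps, t$affine, support)
}
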