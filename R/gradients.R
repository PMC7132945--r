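#' Diffusion gradient table
#'
#' Pairs each acquired volume's b-value (s/mm^2) with its unit gradient
#' direction. Directions with b > 0 are renormalised to unit length; at
#' least one b = 0 entry is required so a tensor fit has a baseline signal.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix (n x 3) of gradient directions.
#' @return A `gradient_table` object (list with `bvals`, `bvecs`).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (length(bvals) != nrow(bvecs)) {
    stop(sprintf("format error: %d b-values but %d gradient rows",
                 length(bvals), nrow(bvecs)), call. = FALSE)
  }
  if (any(bvals < 0)) stop("validation error: negative b-value", call. = FALSE)
  if (!any(bvals == 0)) {
    stop("validation error: gradient table has no b = 0 entry", call. = FALSE)
  }
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw & nrm == 0)) {
    stop("validation error: zero gradient vector with b > 0", call. = FALSE)
  }
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(round(x$bvals)))
  cat(sprintf("<gradient_table> %d volumes; shells b = %s s/mm^2\n",
              length(x$bvals), paste(shells, collapse = ", ")))
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Build a single-shell gradient scheme with uniformly spread directions
#'
#' Directions are placed on a spherical Fibonacci lattice, which spreads
#' points near-uniformly over the sphere and is fully deterministic.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param bval shell b-value (s/mm^2).
#' @param n_b0 number of interleaved b = 0 volumes (placed first).
#' @return A [gradient_table()].
#' @export
make_gradient_scheme <- function(n_dirs = 30, bval = 1000, n_b0 = 6) {
  stopifnot(n_dirs >= 6, n_b0 >= 1)
  i <- seq_len(n_dirs) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i
  dirs <- cbind(r * cos(th), r * sin(th), z)
  gradient_table(
    bvals = c(rep(0, n_b0), rep(bval, n_dirs)),
    bvecs = rbind(matrix(0, n_b0, 3), dirs)
  )
}

#' Read FSL-style bvals/bvecs text files
#'
#' Accepts both layouts in the wild: one row of n values (bvals) with a
#' 3 x n bvecs matrix, or n rows of 1 (bvals) with an n x 3 matrix.
#'
#' @param bval_path,bvec_path paths to whitespace-delimited text files.
#' @return A [gradient_table()].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  raw <- as.matrix(utils::read.table(bvec_path))
  dimnames(raw) <- NULL
  if (nrow(raw) == 3 && ncol(raw) != 3) raw <- t(raw)
  if (nrow(raw) == 3 && ncol(raw) == 3 && length(bvals) != 3) raw <- t(raw)
  gradient_table(bvals, raw)
}

#' Write FSL-style bvals/bvecs text files
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths; bvecs are written 3 x n.
#' @return Invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "), bval_path)
  m <- t(gtab$bvecs)
  lines <- apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}
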