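# Comparison of two dependent, overlapping correlations that share one
# variable (e.g. tract-A MD vs memory against tract-B MD vs the same
# memory score), with Cohen's q effect size.

#' Cohen's q for a difference between correlations
#'
#' q = atanh(r1) - atanh(r2), the difference of Fisher z transforms.
#'
#' @param r1,r2 correlations in (-1, 1).
#' @param magnitude report |q| (the usual convention).
#' @return q (or |q|).
#' @export
cohens_q <- function(r1, r2, magnitude = TRUE) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("validation error: correlations must lie strictly in (-1, 1)",
         call. = FALSE)
  }
  q <- atanh(r1) - atanh(r2)
  if (magnitude) abs(q) else q
}

#' Steiger test for two overlapping dependent correlations
#'
#' Steiger's Z1* statistic with the pooled-correlation covariance
#' approximation: both correlations share one variable, r12 is the
#' correlation between the two non-shared variables, and the covariance of
#' the two Fisher z estimates is evaluated at the pooled
#' r-bar = (r1 + r2)/2. For a one-tailed test the direction is taken from
#' the sign of r1 - r2 (the detected effect against its comparison).
#'
#' @param r1,r2 the two correlations sharing a variable.
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (complete cases common to all three).
#' @param tail `"one"` or `"two"`.
#' @return One-row tibble: `r1`, `r2`, `r12`, `n`, `z`, `p`, `q`
#'   (Cohen's q magnitude), `tail`.
#' @export
steiger_dependent_z <- function(r1, r2, r12, n, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (any(abs(c(r1, r2, r12)) >= 1)) {
    stop("validation error: correlations must lie strictly in (-1, 1)",
         call. = FALSE)
  }
  if (n < 10) stop("validation error: need n >= 10", call. = FALSE)
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar <- (r1 + r2) / 2
  psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  cov_z <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_z))
  p <- if (tail == "one") pnorm(-abs(z)) else 2 * pnorm(-abs(z))
  tibble::tibble(r1 = r1, r2 = r2, r12 = r12, n = as.integer(n),
                 z = z, p = p, q = cohens_q(r1, r2), tail = tail)
}
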