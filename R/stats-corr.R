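# Correlation machinery: ICV adjustment, bootstrap Pearson CIs, Spearman,
# and Holm step-down correction.

#' Adjust a regional measure for intracranial volume
#'
#' adjusted_i = raw_i - beta * (ICV_i - mean(ICV)), with beta the
#' least-squares slope of the measure on ICV. Centring on the ICV mean
#' preserves the measure's mean, and the residualisation leaves the
#' adjusted values exactly uncorrelated with ICV.
#'
#' @param measure numeric vector of raw per-subject measures.
#' @param icv numeric vector of intracranial volumes.
#' @return Adjusted measures (same length and mean as `measure`).
#' @export
icv_adjust <- function(measure, icv) {
  stopifnot(length(measure) == length(icv))
  ok <- complete.cases(measure, icv)
  if (sum(ok) < 3) stop("validation error: need n >= 3", call. = FALSE)
  if (var(icv[ok]) == 0) {
    stop("validation error: ICV is constant; slope undefined", call. = FALSE)
  }
  beta <- cov(measure[ok], icv[ok]) / var(icv[ok])
  measure - beta * (icv - mean(icv[ok]))
}

#' Pearson correlation with bootstrap confidence interval
#'
#' r and its two-sided p-value come from the usual t transform with
#' n - 2 degrees of freedom; the 95% CI is the percentile interval of r
#' over `n_boot` paired resamples (bias-corrected-accelerated available
#' via `ci_method = "bca"`). Deterministic under `seed`.
#'
#' @param x,y numeric vectors.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for resampling.
#' @param conf confidence level.
#' @param ci_method `"percentile"` or `"bca"`.
#' @return A `corr_result`: one-row tibble with `r`, `n`, `p`, `ci_lo`,
#'   `ci_hi` plus bootstrap metadata.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 1000, seed = 1L, conf = 0.95,
                              ci_method = c("percentile", "bca")) {
  ci_method <- match.arg(ci_method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("validation error: need n >= 4 complete pairs",
                  call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- cor(x, y)
  p <- pearson_p(r, n)
  rb <- with_preserved_seed(seed, boot_cor(x, y, n_boot))
  alpha <- 1 - conf
  if (ci_method == "percentile") {
    ci <- unname(quantile(rb, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                          type = 6))
  } else {
    ci <- bca_interval(rb, r, x, y, alpha)
  }
  structure(tibble::tibble(r = r, n = n, p = p,
                           ci_lo = ci[1], ci_hi = ci[2],
                           n_boot = n_boot, ci_method = ci_method),
            class = c("corr_result", "tbl_df", "tbl", "data.frame"))
}

pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# Vectorised paired bootstrap of the correlation: one n_boot x n index
# matrix, correlation per row from moment sums.
boot_cor <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  xb <- matrix(x[idx], n_boot, n)
  yb <- matrix(y[idx], n_boot, n)
  sx <- rowSums(xb); sy <- rowSums(yb)
  sxx <- rowSums(xb^2); syy <- rowSums(yb^2); sxy <- rowSums(xb * yb)
  num <- n * sxy - sx * sy
  den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

# BCa interval from bootstrap replicates (jackknife acceleration).
bca_interval <- function(rb, r_hat, x, y, alpha) {
  rb <- rb[is.finite(rb)]
  z0 <- qnorm(mean(rb < r_hat))
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) cor(x[-i], y[-i]), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  unname(quantile(rb, adj, na.rm = TRUE, type = 6))
}

#' Spearman rank correlation
#'
#' Average ranks on ties, then the Pearson machinery (t transform with
#' n - 2 df) on the ranks -- the large-sample approximation robust to
#' monotone nonlinearity and outliers.
#'
#' @param x,y numeric vectors.
#' @return One-row tibble with `rho`, `n`, `p`.
#' @export
spearman_corr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("validation error: need n >= 4 complete pairs",
                  call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  rho <- cor(rx, ry)
  tibble::tibble(rho = rho, n = n, p = pearson_p(rho, n))
}

#' Holm step-down adjustment
#'
#' Bonferroni-Holm over a declared family of size `m` (which may exceed
#' the number of p-values supplied, e.g. when only the computable members
#' of a 6- or 15-test family are present). Returns adjusted p-values in
#' the original order.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param m family size (defaults to `length(pvals)`).
#' @return Adjusted p-values.
#' @export
holm_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(pvals)) {
    stop("validation error: family size m smaller than number of p-values",
         call. = FALSE)
  }
  p.adjust(pvals, method = "holm", n = m)
}
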