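# The full structure-cognition statistics layer over a cohort table:
# complete-case restriction, per-tract bootstrap Pearson families with
# Holm correction, Steiger comparisons of any significant association
# against the other tract, ICV-adjusted volume-cognition family, and the
# sensitivity block (Spearman, boxplot-rule outliers, Bayes factor).

#' Run the structure-cognition analysis over a cohort table
#'
#' Expects one row per subject with tract metrics (`<tract>_fa`,
#' `<tract>_md`), memory scores, regional volumes (`vol_*`) and `icv`.
#' Subjects missing either tract's metrics are dropped first (complete-case
#' restriction across tracts, so dependent correlations are comparable).
#' Per tract, the 2 metrics x 3 tasks Pearson family (m = 6) is
#' bootstrap-CI'd and Holm-corrected; each significant association is then
#' compared against the other tract's corresponding correlation with a
#' one-tailed Steiger test and Cohen's q. Volume-cognition correlations
#' use ICV-adjusted volumes and Holm over m = 15. The sensitivity block
#' re-examines each significant association with Spearman's rho, a
#' 1.5 x IQR boxplot-rule outlier re-run, and the default correlation
#' Bayes factor.
#'
#' @param cohort cohort tibble (see [make_cohort()] for the column
#'   contract).
#' @param tracts character vector of tract prefixes (first two are
#'   compared against each other).
#' @param tasks character vector of score columns.
#' @param n_boot bootstrap resamples per correlation.
#' @param seed RNG seed for all bootstraps.
#' @param alpha significance threshold applied to Holm-adjusted p-values.
#' @param sensitivity run the Spearman/outlier/Bayes block.
#' @return A `structure_cognition_analysis`: list of tibbles
#'   `correlations`, `comparisons`, `volume_correlations`, `sensitivity`,
#'   plus `n_complete` and settings.
#' @export
run_structure_cognition_analysis <- function(cohort,
                                             tracts = c("dhc", "ac"),
                                             tasks = c("cpwm", "psmt", "lswmt"),
                                             n_boot = 1000, seed = 1L,
                                             alpha = 0.05,
                                             sensitivity = TRUE) {
  metric_cols <- as.vector(outer(tracts, c("fa", "md"), paste, sep = "_"))
  needed <- c(metric_cols, tasks)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("schema error: cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cc <- cohort[complete.cases(cohort[, needed]), , drop = FALSE]
  n <- nrow(cc)

  # (1) per-tract structure-cognition families, m = 6 each
  fam <- tidyr::expand_grid(tract = tracts, metric = c("fa", "md"),
                            task = tasks)
  res <- purrr::pmap_dfr(fam, function(tract, metric, task) {
    col <- paste(tract, metric, sep = "_")
    cr <- pearson_bootstrap(cc[[col]], cc[[task]], n_boot = n_boot,
                            seed = seed)
    tibble::tibble(tract = tract, metric = metric, task = task,
                   r = cr$r, n = cr$n, p = cr$p,
                   ci_lo = cr$ci_lo, ci_hi = cr$ci_hi)
  })
  res <- res |>
    dplyr::group_by(.data$tract) |>
    dplyr::mutate(m = dplyr::n(),
                  p_holm = holm_adjust(.data$p, m = dplyr::n()[1])) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_holm < alpha)

  # (2) Steiger comparison of each significant association against the
  # corresponding correlation in the other tract
  comparisons <- NULL
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig) && length(tracts) >= 2) {
    comparisons <- purrr::pmap_dfr(
      sig[, c("tract", "metric", "task", "r")],
      function(tract, metric, task, r) {
        other <- setdiff(tracts, tract)[1]
        col1 <- paste(tract, metric, sep = "_")
        col2 <- paste(other, metric, sep = "_")
        r2 <- cor(cc[[col2]], cc[[task]])
        r12 <- cor(cc[[col1]], cc[[col2]])
        st <- steiger_dependent_z(r, r2, r12, n, tail = "one")
        dplyr::bind_cols(
          tibble::tibble(tract = tract, other_tract = other,
                         metric = metric, task = task), st)
      })
  }
  if (is.null(comparisons)) {
    comparisons <- tibble::tibble(tract = character(), other_tract = character(),
                                  metric = character(), task = character(),
                                  r1 = double(), r2 = double(), r12 = double(),
                                  n = integer(), z = double(), p = double(),
                                  q = double(), tail = character())
  }

  # (3) ICV-adjusted volume-cognition family, m = 15
  vol_cols <- grep("^vol_", names(cc), value = TRUE)
  volume_correlations <- tibble::tibble()
  if (length(vol_cols) && "icv" %in% names(cc)) {
    vfam <- tidyr::expand_grid(volume = vol_cols, task = tasks)
    m_vol <- nrow(vfam)
    volume_correlations <- purrr::pmap_dfr(vfam, function(volume, task) {
      adj <- icv_adjust(cc[[volume]], cc$icv)
      cr <- pearson_bootstrap(adj, cc[[task]], n_boot = n_boot, seed = seed)
      tibble::tibble(volume = sub("^vol_", "", volume), task = task,
                     r = cr$r, n = cr$n, p = cr$p,
                     ci_lo = cr$ci_lo, ci_hi = cr$ci_hi)
    })
    volume_correlations$m <- m_vol
    volume_correlations$p_holm <- holm_adjust(volume_correlations$p,
                                              m = m_vol)
    volume_correlations$significant <- volume_correlations$p_holm < alpha
  }

  # (4) sensitivity block for each significant structure-cognition pair
  sens <- tibble::tibble()
  if (sensitivity && nrow(sig)) {
    sens <- purrr::pmap_dfr(
      sig[, c("tract", "metric", "task")],
      function(tract, metric, task) {
        col <- paste(tract, metric, sep = "_")
        x <- cc[[col]]; y <- cc[[task]]
        sp <- spearman_corr(x, y)
        out <- boxplot_outliers(x)
        keep <- !out
        r_noout <- if (sum(keep) >= 4) cor(x[keep], y[keep]) else NA_real_
        p_noout <- if (sum(keep) >= 4) pearson_p(r_noout, sum(keep)) else NA_real_
        bf <- correlation_bf10(cor(x, y), length(x))
        tibble::tibble(tract = tract, metric = metric, task = task,
                       spearman_rho = sp$rho, spearman_p = sp$p,
                       n_outliers = sum(out),
                       r_no_outliers = r_noout, p_no_outliers = p_noout,
                       bf10 = bf$bf10, bci_lo = bf$ci_lo, bci_hi = bf$ci_hi)
      })
  }

  structure(list(correlations = res, comparisons = comparisons,
                 volume_correlations = volume_correlations,
                 sensitivity = sens,
                 n_complete = n, alpha = alpha, n_boot = n_boot,
                 seed = seed),
            class = "structure_cognition_analysis")
}

# Boxplot (Tukey fence) rule: flag values beyond 1.5 x IQR of the
# quartiles; flagged cases feed a sensitivity re-run, never the headline
# analysis.
boxplot_outliers <- function(x, k = 1.5) {
  qs <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- qs[2] - qs[1]
  x < qs[1] - k * iqr | x > qs[2] + k * iqr
}

#' @export
print.structure_cognition_analysis <- function(x, ...) {
  cat(sprintf("<structure_cognition_analysis> n = %d complete cases\n",
              x$n_complete))
  cat(sprintf("  %d structure-cognition correlations (%d significant after Holm, alpha = %g)\n",
              nrow(x$correlations), sum(x$correlations$significant),
              x$alpha))
  if (nrow(x$comparisons)) {
    cat(sprintf("  %d dependent-correlation comparison(s)\n",
                nrow(x$comparisons)))
  }
  if (nrow(x$volume_correlations)) {
    cat(sprintf("  %d volume-cognition correlations (%d significant)\n",
                nrow(x$volume_correlations),
                sum(x$volume_correlations$significant)))
  }
  invisible(x)
}
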