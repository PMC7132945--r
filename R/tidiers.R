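# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @exportS3Method generics::tidy
tidy.structure_cognition_analysis <- function(x, which = c("correlations",
                                                           "comparisons",
                                                           "volume_correlations",
                                                           "sensitivity"),
                                              ...) {
  which <- match.arg(which)
  tibble::as_tibble(x[[which]])
}

#' @exportS3Method generics::glance
glance.structure_cognition_analysis <- function(x, ...) {
  tibble::tibble(
    n_complete = x$n_complete,
    n_correlations = nrow(x$correlations),
    n_significant = sum(x$correlations$significant),
    n_comparisons = nrow(x$comparisons),
    n_volume_tests = nrow(x$volume_correlations),
    alpha = x$alpha,
    n_boot = x$n_boot)
}

#' @exportS3Method generics::tidy
tidy.corr_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p,
                 conf.low = x$ci_lo, conf.high = x$ci_hi,
                 n = x$n, method = paste0("pearson+bootstrap(", x$ci_method, ")"))
}

#' @exportS3Method generics::glance
glance.corr_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot)
}

#' @exportS3Method generics::tidy
tidy.bayes_corr_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, bf10 = x$bf10,
                 cred.low = x$ci_lo, cred.high = x$ci_hi,
                 n = x$n, prior_width = x$kappa)
}

#' Forest-style plot of structure-cognition correlations
#'
#' Point estimates with bootstrap CIs per tract/metric/task; Holm-surviving
#' associations are filled.
#'
#' @param object a `structure_cognition_analysis`.
#' @param ... ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.structure_cognition_analysis <- function(object, ...) {
  d <- object$correlations |>
    dplyr::mutate(label = paste(toupper(.data$tract),
                                toupper(.data$metric), .data$task,
                                sep = " "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "black"),
                               name = "Holm-significant") +
    ggplot2::labs(x = "Pearson r (bootstrap 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a tractogram projection
#'
#' Streamlines projected onto one anatomical plane; a quick debug
#' rendering, not a viewer.
#'
#' @param t a [tractogram()].
#' @param plane `"axial"` (x-y), `"coronal"` (x-z) or `"sagittal"` (y-z).
#' @param max_streamlines subsample cap for plotting speed.
#' @return A ggplot object.
#' @export
plot_tractogram <- function(t, plane = c("axial", "coronal", "sagittal"),
                            max_streamlines = 500) {
  plane <- match.arg(plane)
  axes <- switch(plane, axial = c(1, 2), coronal = c(1, 3),
                 sagittal = c(2, 3))
  sl <- t$streamlines
  if (length(sl) > max_streamlines) {
    sl <- sl[seq(1, length(sl), length.out = max_streamlines)]
  }
  d <- purrr::imap_dfr(sl, function(s, i) {
    tibble::tibble(id = i, a = s[, axes[1]], b = s[, axes[2]])
  })
  lab <- c("x (mm)", "y (mm)", "z (mm)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  group = .data$id)) +
    ggplot2::geom_path(alpha = 0.25, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[axes[1]], y = lab[axes[2]]) +
    ggplot2::theme_minimal()
}
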