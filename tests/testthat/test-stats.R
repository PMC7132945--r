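# Statistics layer: ICV adjustment, correlations, Holm, Steiger/Cohen q,
# Bayes factor, and the full analysis pipeline.

test_that("ICV adjustment leaves measures exactly uncorrelated with ICV", {
  set.seed(14)
  icv <- rnorm(200, 1.59e6, 1.77e5)
  meas <- 5000 + 0.002 * icv + rnorm(200, 0, 300)
  adj <- icv_adjust(meas, icv)
  expect_lt(abs(cor(adj, icv)), 1e-10)
  expect_equal(mean(adj), mean(meas), tolerance = 1e-12)
  # beta = 0 exactly: output equals input
  x <- c(1, 2, 3, 4); icv0 <- c(10, 11, 9, 10)
  x_orth <- x - (cov(x, icv0) / var(icv0)) * icv0
  expect_equal(icv_adjust(x_orth, icv0), x_orth, tolerance = 1e-12)
  # a subject at the ICV mean is untouched
  icv2 <- c(900, 1000, 1100, 1000)
  meas2 <- c(5, 9, 6, 7)
  adj2 <- icv_adjust(meas2, icv2)
  expect_equal(adj2[icv2 == mean(icv2)], meas2[icv2 == mean(icv2)],
               tolerance = 1e-12)
  expect_error(icv_adjust(meas2, rep(1, 4)), "constant")
})

test_that("collinear and orthogonal inputs give exact correlations", {
  x <- 1:20
  r1 <- pearson_bootstrap(x, 2 * x + 1, n_boot = 200, seed = 1)
  expect_equal(r1$r, 1)
  expect_equal(c(r1$ci_lo, r1$ci_hi), c(1, 1))
  # constructed orthogonality
  x2 <- c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2)
  y2 <- c(1, 1, 1, 1, 1, -1, -1, -1, -1, -1)
  expect_lt(abs(pearson_bootstrap(x2, y2, n_boot = 100, seed = 1)$r), 1e-12)
  expect_error(pearson_bootstrap(rep(1, 10), 1:10), "zero variance")
})

test_that("bootstrap CIs are deterministic under seed and sane", {
  set.seed(7)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  a <- pearson_bootstrap(x, y, seed = 42)
  b <- pearson_bootstrap(x, y, seed = 42)
  expect_identical(a, b)
  expect_lt(a$ci_lo, a$r); expect_gt(a$ci_hi, a$r)
  d <- pearson_bootstrap(x, y, seed = 43)
  expect_false(identical(a$ci_lo, d$ci_lo))
  bca <- pearson_bootstrap(x, y, seed = 42, ci_method = "bca")
  expect_lt(bca$ci_lo, bca$ci_hi)
})

test_that("two-sided p matches the t transform used by cor.test", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    ours <- pearson_bootstrap(x, y, n_boot = 50, seed = 1)
    ref <- cor.test(x, y)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("Spearman handles monotone transforms, reversals and ties", {
  x <- seq(0.1, 3, length.out = 15)
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  expect_equal(spearman_corr(x, rev(x))$rho, -1)
  # tied-rank fixture: hand-computed from average ranks
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(10, 20, 25, 30, 40, 38)
  rx <- c(1, 2.5, 2.5, 4, 5.5, 5.5)
  ry <- c(1, 2, 3, 4, 6, 5)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_corr(xt, yt)$rho, hand, tolerance = 1e-12)
  expect_equal(spearman_corr(xt, yt)$rho,
               unname(cor(xt, yt, method = "spearman")), tolerance = 1e-12)
})

test_that("Holm adjustment matches the hand-stepped definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03), m = 3),
               c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.04, m = 1), 0.04)
  # dominated by plain Bonferroni, monotone on sorted input
  set.seed(17)
  for (i in 1:20) {
    p <- runif(6)
    adj <- holm_adjust(p, m = 6)
    expect_true(all(adj <= pmin(6 * p, 1) + 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p))
  }
  # declared family larger than the supplied p-values
  expect_equal(holm_adjust(0.01, m = 15), 0.15)
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Cohen's q reproduces the printed correlation-pair effect sizes", {
  expect_equal(round(cohens_q(-0.269, 0.100), 3), 0.376)
  expect_equal(round(cohens_q(-0.269, -0.072), 3), 0.204)
  expect_equal(round(cohens_q(-0.269, -0.047), 3), 0.229)
  expect_equal(cohens_q(0.3, 0.3), 0)
  expect_equal(cohens_q(-0.269, 0.1, magnitude = FALSE),
               atanh(-0.269) - atanh(0.1), tolerance = 1e-15)
  expect_error(cohens_q(1, 0.5), "strictly")
})

test_that("Steiger Z matches an independently coded textbook formula", {
  # independent oracle: direct transcription of the pooled-r covariance
  # form for overlapping correlations
  oracle <- function(r1, r2, r12, n) {
    rb2 <- ((r1 + r2) / 2)^2
    c_num <- r12 * (1 - 2 * rb2) - 0.5 * rb2 * (1 - 2 * rb2 - r12^2)
    cv <- c_num / (1 - rb2)^2
    (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * cv))
  }
  st <- steiger_dependent_z(0.5, 0.3, 0.4, 100)
  expect_equal(st$z, oracle(0.5, 0.3, 0.4, 100), tolerance = 1e-10)
  set.seed(23)
  for (i in 1:20) {
    r1 <- runif(1, -0.8, 0.8); r2 <- runif(1, -0.8, 0.8)
    r12 <- runif(1, -0.6, 0.6); n <- sample(20:500, 1)
    expect_equal(steiger_dependent_z(r1, r2, r12, n)$z,
                 oracle(r1, r2, r12, n), tolerance = 1e-10)
  }
  # equal correlations give Z = 0 and q = 0 for any r12 and n
  for (r12 in c(-0.5, 0, 0.7)) {
    st0 <- steiger_dependent_z(0.42, 0.42, r12, 57)
    expect_equal(st0$z, 0)
    expect_equal(st0$q, 0)
  }
  expect_equal(steiger_dependent_z(0.5, 0.3, 0.4, 100, tail = "two")$p,
               2 * steiger_dependent_z(0.5, 0.3, 0.4, 100, tail = "one")$p,
               tolerance = 1e-12)
  expect_error(steiger_dependent_z(0.5, 0.3, 0.4, 5), "n >= 10")
})

test_that("comparison sensitivity grows with the overlap correlation", {
  # with r12 -> 1 the two correlations are nearly the same quantity
  # measured twice, so a fixed difference becomes more significant;
  # monotonicity in r12 at fixed r1 > r2:
  zs <- vapply(c(0.1, 0.4, 0.7), function(r12) {
    abs(steiger_dependent_z(0.5, 0.3, r12, 80)$z)
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("the correlation Bayes factor matches an independent quadrature", {
  trapz_oracle <- function(r, n, kappa = 1) {
    rho <- seq(-1 + 1e-8, 1 - 1e-8, length.out = 200001)
    f <- exp(dissectr:::log_lik_ratio_rho(rho, r, n)) *
      dissectr:::stretched_beta_density(rho, kappa)
    sum((f[-1] + f[-length(f)]) / 2) * diff(rho[1:2])
  }
  for (case in list(c(-0.269, 95), c(0.3, 40), c(-0.1, 200), c(0.6, 25))) {
    bf <- correlation_bf10(case[1], case[2])
    expect_equal(bf$bf10, trapz_oracle(case[1], case[2]),
                 tolerance = 1e-6)
  }
})

test_that("the Bayes factor behaves monotonically in evidence", {
  # null data: BF10 shrinks with n
  expect_lt(correlation_bf10(0, 50)$bf10, 1)
  expect_lt(correlation_bf10(0, 500)$bf10, correlation_bf10(0, 50)$bf10)
  # clearly nonzero r: BF10 grows with n
  expect_gt(correlation_bf10(0.4, 200)$bf10, correlation_bf10(0.4, 50)$bf10)
  bf <- correlation_bf10(-0.269, 95)
  expect_lt(bf$ci_lo, bf$ci_hi)
  expect_gt(bf$ci_lo, -1); expect_lt(bf$ci_hi, 1)
  expect_lt(bf$ci_hi, 0)  # posterior mass below zero for negative r
  expect_error(correlation_bf10(1.2, 50), "\\|r\\|")
})

test_that("the analysis pipeline flags the planted association", {
  co <- make_cohort(cohort_spec(n_subjects = 95,
                                true_corr_md_memory = -0.4), seed = 5)
  res <- run_structure_cognition_analysis(co, n_boot = 200, seed = 1)
  expect_s3_class(res, "structure_cognition_analysis")
  expect_equal(res$n_complete, 95)
  expect_equal(nrow(res$correlations), 12)   # 2 tracts x 2 metrics x 3 tasks
  hit <- res$correlations[res$correlations$tract == "dhc" &
                            res$correlations$metric == "md" &
                            res$correlations$task == "cpwm", ]
  expect_true(hit$significant)
  # the comparison block compares against the other tract and reports q
  cmp <- res$comparisons[res$comparisons$metric == "md" &
                           res$comparisons$task == "cpwm", ]
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$other_tract, "ac")
  expect_equal(cmp$q, abs(atanh(cmp$r1) - atanh(cmp$r2)), tolerance = 1e-12)
  # sensitivity block carries Spearman, outlier re-run and BF10
  sens <- res$sensitivity[res$sensitivity$metric == "md", ]
  expect_gte(nrow(sens), 1)
  expect_true(all(is.finite(sens$bf10)))
  # volume family: 5 regions x 3 tasks with Holm over 15
  expect_equal(nrow(res$volume_correlations), 15)
  expect_true(all(res$volume_correlations$p_holm >=
                    res$volume_correlations$p))
})

test_that("detection power at the planted effect size is high", {
  hits <- 0; n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    co <- make_cohort(cohort_spec(n_subjects = 95,
                                  true_corr_md_memory = -0.4), seed = 100 + s)
    res <- run_structure_cognition_analysis(co, n_boot = 50, seed = 1,
                                            sensitivity = FALSE)
    hit <- res$correlations[res$correlations$tract == "dhc" &
                              res$correlations$metric == "md" &
                              res$correlations$task == "cpwm", ]
    if (hit$significant) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("the pipeline errors cleanly on schema violations and runs fast", {
  co <- make_cohort(seed = 2)
  co$dhc_md <- NULL
  expect_error(run_structure_cognition_analysis(co), "schema error")
  co2 <- make_cohort(seed = 2)
  elapsed <- system.time(
    run_structure_cognition_analysis(co2, n_boot = 1000, seed = 1))["elapsed"]
  expect_lt(elapsed, 10)
})

test_that("tidiers expose the result tables in broom shape", {
  co <- make_cohort(seed = 6)
  res <- run_structure_cognition_analysis(co, n_boot = 100, seed = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("tract", "metric", "task", "r", "p_holm") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_complete, 95)
  cr <- pearson_bootstrap(co$dhc_md, co$cpwm, n_boot = 100, seed = 1)
  expect_true(all(c("estimate", "conf.low", "conf.high") %in%
                    names(tidy(cr))))
  bf <- correlation_bf10(-0.3, 50)
  expect_true("bf10" %in% names(tidy(bf)))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
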