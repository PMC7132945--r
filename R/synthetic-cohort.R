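# Synthetic cohort generator: per-subject tract microstructure, memory
# scores, regional volumes and intracranial volume, with one planted
# structure-cognition effect and ICV-confounded volumes. Default scales
# follow the reference human cohort: n = 95 complete cases, commissural
# MD 1.478e-3 (SD 0.163e-3) mm^2/s, recognition-memory score 35.79
# (SD 2.78), ICV 1 587 548 (SD 176 652) mm^3.

#' Cohort simulation settings
#'
#' @param n_subjects subjects to draw.
#' @param true_corr_md_memory planted correlation between the first
#'   tract's MD and the first memory score (rho in (-1, 1)).
#' @param md_mean,md_sd MD scale of the planted tract (mm^2/s).
#' @param score_mean,score_sd memory-score scale.
#' @param icv_mean,icv_sd intracranial volume scale (mm^3).
#' @param volume_icv_r correlation between each regional volume and ICV
#'   (the confound the ICV adjustment removes); the implied slope gamma is
#'   `volume_icv_r * vol_sd / icv_sd` per region.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 95,
                        true_corr_md_memory = -0.269,
                        md_mean = 1.478e-3, md_sd = 0.163e-3,
                        score_mean = 35.79, score_sd = 2.78,
                        icv_mean = 1587548.46, icv_sd = 176651.55,
                        volume_icv_r = 0.5) {
  if (abs(true_corr_md_memory) >= 1) {
    stop("validation error: |rho| must be < 1", call. = FALSE)
  }
  if (any(c(md_sd, score_sd, icv_sd) <= 0)) {
    stop("validation error: all SDs must be > 0", call. = FALSE)
  }
  if (n_subjects < 4) {
    stop("validation error: need n >= 4 subjects for correlations",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 true_corr_md_memory = true_corr_md_memory,
                 md_mean = md_mean, md_sd = md_sd,
                 score_mean = score_mean, score_sd = score_sd,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 volume_icv_r = volume_icv_r),
            class = "cohort_spec")
}

# Reference scales for the remaining (null) variables.
cohort_reference <- list(
  tracts = list(
    dhc = list(fa = c(0.318, 0.059), md = c(1.478e-3, 0.163e-3)),
    ac = list(fa = c(0.439, 0.050), md = c(0.854e-3, 0.051e-3))),
  tasks = list(
    cpwm = c(35.79, 2.78), psmt = c(112.15, 14.34), lswmt = c(110.15, 11.49)),
  volumes = list(
    hippocampus = c(8856.07, 663.78), amygdala = c(3210.26, 310.89),
    entorhinal = c(3460.21, 575.65), parahippocampal = c(4391.78, 523.85),
    temporal_pole = c(4682.52, 490.93)))

#' Draw a synthetic cohort table
#'
#' `dhc_md` and `cpwm` are bivariate normal with the planted correlation;
#' all other tract metrics and scores are independent draws at the
#' reference scales; each regional volume is `gamma * ICV` plus
#' independent noise, giving a volume-ICV correlation of
#' `spec$volume_icv_r`. Deterministic under `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @return Tibble with columns `subject`, `dhc_fa`, `dhc_md`, `ac_fa`,
#'   `ac_md`, `cpwm`, `psmt`, `lswmt`, `vol_*` (five regions) and `icv`.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  ref <- cohort_reference
  with_preserved_seed(seed, {
    rho <- spec$true_corr_md_memory
    z1 <- rnorm(n); z2 <- rnorm(n)
    md_std <- z1
    score_std <- rho * z1 + sqrt(1 - rho^2) * z2
    dhc_md <- spec$md_mean + spec$md_sd * md_std
    cpwm <- spec$score_mean + spec$score_sd * score_std

    icv <- rnorm(n, spec$icv_mean, spec$icv_sd)
    vols <- lapply(ref$volumes, function(ms) {
      gamma <- spec$volume_icv_r * ms[2] / spec$icv_sd
      ms[1] + gamma * (icv - spec$icv_mean) +
        rnorm(n, 0, ms[2] * sqrt(1 - spec$volume_icv_r^2))
    })

    out <- tibble::tibble(
      subject = sprintf("S%03d", seq_len(n)),
      dhc_fa = rnorm(n, ref$tracts$dhc$fa[1], ref$tracts$dhc$fa[2]),
      dhc_md = dhc_md,
      ac_fa = rnorm(n, ref$tracts$ac$fa[1], ref$tracts$ac$fa[2]),
      ac_md = rnorm(n, ref$tracts$ac$md[1], ref$tracts$ac$md[2]),
      cpwm = cpwm,
      psmt = rnorm(n, ref$tasks$psmt[1], ref$tasks$psmt[2]),
      lswmt = rnorm(n, ref$tasks$lswmt[1], ref$tasks$lswmt[2]))
    for (nm in names(vols)) out[[paste0("vol_", nm)]] <- vols[[nm]]
    out$icv <- icv
    out
  })
}
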