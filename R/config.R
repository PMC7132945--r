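# Run configuration: YAML key/value sections per pipeline stage, with
# defaults mirroring the study protocols (step 0.5 mm human / 0.1 mm
# ex vivo, 60 degree angle threshold, 4x4x4 supersampled seeding, 1000
# bootstrap resamples, alpha 0.05).

default_config <- function() {
  list(
    tracking = list(
      step_size_mm = 0.5,          # human flavour; ex vivo uses 0.1
      angle_threshold_deg = 60,
      supersample_per_axis = 4L,
      max_length_mm = 250,
      min_vertices = 3L,
      fa_floor = 0.1
    ),
    dissection = list(
      cut_offset_slices = 5L,      # sagittal cut planes, slices from midline
      and_mode = "passage"         # or "terminate"
    ),
    stats = list(
      n_boot = 1000L,
      alpha = 0.05,
      ci_method = "percentile",    # or "bca"
      bayes_prior_width = 1
    )
  )
}

config_ranges <- list(
  tracking = list(
    step_size_mm = c(1e-6, 10),
    angle_threshold_deg = c(1e-6, 180 - 1e-9),
    supersample_per_axis = c(1, 16),
    max_length_mm = c(1e-3, Inf),
    min_vertices = c(2, Inf),
    fa_floor = c(0, 1)
  ),
  dissection = list(cut_offset_slices = c(1, Inf)),
  stats = list(
    n_boot = c(10, Inf),
    alpha = c(0, 1),
    bayes_prior_width = c(1e-6, 100)
  )
)

#' Load and validate a run configuration
#'
#' Reads a YAML config with sections `tracking`, `dissection` and `stats`,
#' fills unset keys with protocol defaults, rejects unknown keys and
#' out-of-range values.
#'
#' @param path YAML file; `NULL` or an empty file yields the full defaults.
#' @return Nested list of validated parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad_sections <- setdiff(names(user), names(cfg))
  if (length(bad_sections)) {
    stop(sprintf("validation error: unknown config section(s): %s",
                 paste(bad_sections, collapse = ", ")), call. = FALSE)
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad)) {
      stop(sprintf("validation error: unknown key(s) in [%s]: %s",
                   sec, paste(bad, collapse = ", ")), call. = FALSE)
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (sec in names(config_ranges)) {
    for (key in names(config_ranges[[sec]])) {
      v <- cfg[[sec]][[key]]
      rng <- config_ranges[[sec]][[key]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v) && is.finite(rng[2]) ||
          v < rng[1] || v > rng[2]) {
        stop(sprintf(
          "validation error: %s.%s = %s outside allowed range [%g, %g]",
          sec, key, format(v), rng[1], rng[2]), call. = FALSE)
      }
    }
  }
  if (!cfg$dissection$and_mode %in% c("passage", "terminate")) {
    stop("validation error: dissection.and_mode must be 'passage' or 'terminate'",
         call. = FALSE)
  }
  if (!cfg$stats$ci_method %in% c("percentile", "bca")) {
    stop("validation error: stats.ci_method must be 'percentile' or 'bca'",
         call. = FALSE)
  }
  invisible(cfg)
}
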