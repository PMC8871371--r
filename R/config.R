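#' Default run configuration
#'
#' The full parameter surface of the pipeline as one nested list, mirroring
#' every module default. A run configuration file (YAML or JSON) may
#' override any subset of these keys; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param seed Master seed for the whole run.
#' @return Nested named list with blocks `simulate`, `irf`, `fit`,
#'   `segment`, `endpoints`, `stats` and top-level `seed`.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_days = 2L, larvae_per_day = 3L, cells_per_larva = 8L,
      shape = c(64L, 64L), radius_range = c(3, 4.5),
      tnfa_prop = 0.5, effect = 0.15,
      day_shift_sd = 0.02, larva_sd = 0.02,
      budget = 5000, background_offset = 0.1,
      treatment = "wound",
      n_bins = 256L, window_ns = 12.5,
      reporter_noise_sd = 0.01
    ),
    irf = list(fwhm_ps = 260, peak_bin = 25L),
    fit = list(threshold = 500, binning = 1L, objective = "neyman",
               wrap = FALSE),
    segment = list(threshold = 0.15, min_area = 25L,
                   gfp_threshold = NULL, bacteria_threshold = NULL,
                   exclude_bacteria = FALSE),
    endpoints = list(min_valid_pixels = 5L, omi_by = NULL),
    stats = list(outcome = c("orr", "nadph_tm", "nadph_alpha1"),
                 treatment = "tnfa_status", block = "day_id",
                 cluster = "larva_id", log_transform = FALSE,
                 interaction = FALSE)
  )
}

#' Read and validate a run configuration file
#'
#' Parses YAML (`.yml`/`.yaml`) or JSON, checks every key against
#' [default_config()] (unknown keys are an error naming the offending
#' path), and fills unset keys with their defaults.
#'
#' @param path Configuration file path.
#' @return A complete configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext),
         call. = FALSE)
  )
  merge_config(default_config(), cfg)
}

merge_config <- function(defaults, override, path = character()) {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s",
                 paste(paste(c(path, unknown[1]), collapse = "$"),
                       collapse = ", ")), call. = FALSE)
  }
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     c(path, nm))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}
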