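# Single structured config for the whole pipeline. Every analysis constant
# defaults to the study's published value; unknown keys are rejected so
# typos cannot silently fall back to defaults.

default_config <- function() {
  list(
    analysis = list(
      plp_window_start_ms = 367,
      plp_window_end_ms = 2500,
      plp_min_valid_fraction = 0.3,
      gaze_max_gap_samples = 14,     # strictly shorter than this is filled
      plp_min_pairs = 4,
      pupil_range_mm = c(1.5, 9),    # inclusive keep-range
      pupil_median_k = 14,
      pupil_max_gap_samples = 14,    # gaps up to and including this filled
      mm_baseline_ms = 360,
      mm_window_ms = 1200,
      mm_max_missing = 0.5,
      mm_min_trials = 5,
      mm_sign_convention = "incongruent_minus_congruent",
      cdi_min_answered_fraction = 0.9
    ),
    geometry = list(
      width_mm = 487, height_mm = 274, width_px = 1920, height_px = 1080,
      viewing_distance_mm = 600, sample_rate_hz = 120
    ),
    aoi = list(width_deg = 11, height_deg = 13.6, center_offset_deg = 8),
    design = list(n_pairs = 8, reps_per_picture = 2, strict_side = FALSE,
                  n_words = 16, reps_per_condition = 2),
    sim = list()                      # overrides for sim_config()
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every missing key with its default (the study's published value for
#' all analysis thresholds), rejects unknown keys, and checks ranges.
#'
#' @param config A named list, a path to a YAML file, or `NULL` for all
#'   defaults.
#' @return The normalized configuration list (class `wordgaze_config`).
#' @export
#' @examples
#' cfg <- validate_config(NULL)
#' cfg$analysis$plp_window_start_ms
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- default_config()
  bad_top <- setdiff(names(config), names(def))
  if (length(bad_top))
    stop("unknown config keys: ", paste(bad_top, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "sim") next  # validated by sim_config()
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop("unknown config keys in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg <- modifyList(def, config)
  a <- cfg$analysis
  errs <- character(0)
  if (a$plp_window_end_ms <= a$plp_window_start_ms ||
      a$plp_window_start_ms < 0)
    errs <- c(errs, "analysis.plp_window_start_ms/plp_window_end_ms")
  if (a$plp_min_valid_fraction < 0 || a$plp_min_valid_fraction > 1)
    errs <- c(errs, "analysis.plp_min_valid_fraction")
  if (a$gaze_max_gap_samples < 1) errs <- c(errs, "analysis.gaze_max_gap_samples")
  if (a$pupil_max_gap_samples < 0) errs <- c(errs, "analysis.pupil_max_gap_samples")
  if (length(a$pupil_range_mm) != 2 ||
      a$pupil_range_mm[1] >= a$pupil_range_mm[2] || a$pupil_range_mm[1] <= 0)
    errs <- c(errs, "analysis.pupil_range_mm")
  if (a$mm_baseline_ms <= 0 || a$mm_window_ms <= 0)
    errs <- c(errs, "analysis.mm_baseline_ms/mm_window_ms")
  if (a$mm_max_missing < 0 || a$mm_max_missing > 1)
    errs <- c(errs, "analysis.mm_max_missing")
  if (a$mm_min_trials < 1) errs <- c(errs, "analysis.mm_min_trials")
  if (!a$mm_sign_convention %in% c("incongruent_minus_congruent",
                                   "congruent_minus_incongruent"))
    errs <- c(errs, "analysis.mm_sign_convention")
  if (a$cdi_min_answered_fraction < 0 || a$cdi_min_answered_fraction > 1)
    errs <- c(errs, "analysis.cdi_min_answered_fraction")
  g <- cfg$geometry
  if (any(unlist(g) <= 0)) errs <- c(errs, "geometry (all fields positive)")
  if (length(errs))
    stop("config validation failed for: ", paste(errs, collapse = "; "))
  # constructor side checks
  do.call(screen_geometry, cfg$geometry)
  do.call(aoi_layout, cfg$aoi)
  do.call(sim_config, cfg$sim)
  class(cfg) <- c("wordgaze_config", "list")
  cfg
}
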