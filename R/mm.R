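# Mismatch-paradigm pupillometry: range filtering, moving-median smoothing,
# gap interpolation, subtractive baseline correction, window means, and the
# congruency difference score. Pupil usability is encoded as NA in
# pupil_left_mm; the gaze validity flag is untouched by these stages.
#
# Fixed stage order: range filter -> median filter -> interpolate ->
# baseline-correct -> window mean. Permuting the median filter and the
# interpolation changes results next to spike-adjacent gaps, so the order is
# regression-guarded in the tests.

#' Discard physiologically implausible pupil samples
#'
#' Pupil diameters outside the keep-range `[lo, hi]` (default 1.5 to 9 mm,
#' endpoints kept) are set to missing. Gaze fields are untouched.
#'
#' @param stream A [sample_stream()].
#' @param lo,hi Keep-range bounds in mm (inclusive).
#' @return The filtered [sample_stream()].
#' @export
pupil_range_filter <- function(stream, lo = 1.5, hi = 9) {
  p <- stream$pupil_left_mm
  # the tracking flag also gates the pupil signal
  p[!stream$valid] <- NA_real_
  p[!is.na(p) & (p < lo | p > hi)] <- NA_real_
  stream$pupil_left_mm <- p
  stream
}

#' Moving-median smoothing of the pupil trace
#'
#' Each observed pupil value is replaced by the median of the observed values
#' in its k-sample neighbourhood (default 14 samples, about 117 ms at
#' 120 Hz). For even `k` the window is left-biased (one extra sample before
#' the current one); windows are truncated at the trace edges; missing
#' samples stay missing and are skipped when forming each median.
#'
#' @param stream A [sample_stream()].
#' @param k Window length in samples.
#' @return The smoothed [sample_stream()].
#' @export
median_filter <- function(stream, k = 14) {
  stream$pupil_left_mm <- .moving_median(stream$pupil_left_mm, as.integer(k))
  stream
}

#' Interpolate short pupil gaps
#'
#' Missing-pupil runs of length `max_gap` samples or fewer (inclusive,
#' unlike the gaze rule) flanked by observed values are filled linearly.
#'
#' @param stream A [sample_stream()].
#' @param max_gap Longest gap, in samples, that is still filled.
#' @return The interpolated [sample_stream()].
#' @export
interpolate_pupil_gaps <- function(stream, max_gap = 14) {
  stream$pupil_left_mm <- fill_gaps_num(stream$pupil_left_mm, max_gap,
                                        inclusive = TRUE)
  stream
}

mm_baseline_window <- function(spec, baseline_ms = 360) {
  c(start = spec$motion_onset_ms - baseline_ms, end = spec$motion_onset_ms)
}

mm_analysis_window <- function(spec, window_ms = 1200) {
  c(start = spec$motion_offset_ms, end = spec$motion_offset_ms + window_ms)
}

#' Subtractive baseline correction of a pupil trace
#'
#' Subtracts the mean observed pupil diameter over the pre-movement baseline
#' interval (by default the 360 ms ending at occluder motion onset) from the
#' whole trace.
#'
#' @param stream A preprocessed [sample_stream()] on the button-press clock.
#' @param spec One row of a [gen_mm_design()] data.frame.
#' @param baseline_ms Baseline duration in ms.
#' @return A list: `stream` (trace with `pupil_corrected_mm` column),
#'   `baseline_mean_mm`, `valid` (`FALSE` when the baseline is entirely
#'   missing).
#' @export
baseline_correct <- function(stream, spec, baseline_ms = 360) {
  bw <- mm_baseline_window(spec, baseline_ms)
  inb <- stream$t_ms >= bw["start"] & stream$t_ms < bw["end"]
  bvals <- stream$pupil_left_mm[inb]
  bmean <- if (any(!is.na(bvals))) mean(bvals, na.rm = TRUE) else NA_real_
  stream$pupil_corrected_mm <- stream$pupil_left_mm - bmean
  list(stream = stream, baseline_mean_mm = bmean, valid = !is.na(bmean))
}

#' Mean corrected dilation in the analysis window
#'
#' Mean of the observed baseline-corrected samples in the window that starts
#' at occluder motion offset (default duration 1200 ms).
#'
#' @param corrected_stream `stream` element of [baseline_correct()].
#' @param spec One row of a [gen_mm_design()] data.frame.
#' @param window_ms Analysis-window duration in ms.
#' @return Mean corrected dilation in mm (`NA` if no observed sample).
#' @export
window_mean <- function(corrected_stream, spec, window_ms = 1200) {
  aw <- mm_analysis_window(spec, window_ms)
  inw <- corrected_stream$t_ms >= aw["start"] & corrected_stream$t_ms < aw["end"]
  vals <- corrected_stream$pupil_corrected_mm[inw]
  if (!any(!is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Trial-level missingness rule for the mismatch task
#'
#' A trial is kept when at most 50% of the samples across the union of the
#' baseline and analysis windows are missing after interpolation; exactly
#' 50% missing is still valid ("more than 50%" is excluded).
#'
#' @param stream Post-interpolation [sample_stream()].
#' @param spec One row of a [gen_mm_design()] data.frame.
#' @param max_missing Largest tolerated missing fraction.
#' @param baseline_ms,window_ms Interval durations in ms.
#' @return Logical flag.
#' @export
trial_validity_mm <- function(stream, spec, max_missing = 0.5,
                              baseline_ms = 360, window_ms = 1200) {
  bw <- mm_baseline_window(spec, baseline_ms)
  aw <- mm_analysis_window(spec, window_ms)
  sel <- (stream$t_ms >= bw["start"] & stream$t_ms < bw["end"]) |
    (stream$t_ms >= aw["start"] & stream$t_ms < aw["end"])
  vals <- stream$pupil_left_mm[sel]
  if (!length(vals)) return(FALSE)
  mean(is.na(vals)) <= max_missing
}

#' Score one mismatch trial
#'
#' Runs the fixed preprocessing order on a raw trial stream and returns the
#' trial-level result row.
#'
#' @param stream Raw [sample_stream()] on the button-press clock.
#' @param spec One row of a [gen_mm_design()] data.frame.
#' @param range_lo,range_hi Pupil keep-range in mm.
#' @param median_k Moving-median window in samples.
#' @param max_gap Pupil interpolation limit in samples.
#' @param baseline_ms,window_ms Interval durations in ms.
#' @param max_missing Trial missingness limit.
#' @return One-row data.frame: `trial_index`, `condition`,
#'   `baseline_mean_mm`, `window_mean_corrected_mm`, `missing_fraction`,
#'   `valid`.
#' @export
score_mm_trial <- function(stream, spec, range_lo = 1.5, range_hi = 9,
                           median_k = 14, max_gap = 14, baseline_ms = 360,
                           window_ms = 1200, max_missing = 0.5) {
  s <- pupil_range_filter(stream, range_lo, range_hi)
  s <- median_filter(s, median_k)
  s <- interpolate_pupil_gaps(s, max_gap)
  bw <- mm_baseline_window(spec, baseline_ms)
  aw <- mm_analysis_window(spec, window_ms)
  sel <- (s$t_ms >= bw["start"] & s$t_ms < bw["end"]) |
    (s$t_ms >= aw["start"] & s$t_ms < aw["end"])
  miss <- if (any(sel)) mean(is.na(s$pupil_left_mm[sel])) else 1
  bc <- baseline_correct(s, spec, baseline_ms)
  wm <- if (bc$valid) window_mean(bc$stream, spec, window_ms) else NA_real_
  valid <- miss <= max_missing && bc$valid && !is.na(wm)
  data.frame(trial_index = spec$trial_index, condition = spec$condition,
             baseline_mean_mm = bc$baseline_mean_mm,
             window_mean_corrected_mm = wm,
             missing_fraction = miss, valid = valid,
             stringsAsFactors = FALSE)
}

#' Congruency difference score for one participant
#'
#' Mean corrected dilation per condition over valid trials; the score is
#' incongruent minus congruent, so a positive value means a larger pupil on
#' incongruent (label-violating) trials. Participants need at least
#' `min_trials` valid trials in each condition; otherwise the score is
#' missing and the inclusion flag is `FALSE`.
#'
#' @param trial_results Stacked [score_mm_trial()] rows.
#' @param min_trials Minimum valid trials per condition.
#' @param sign_convention `"incongruent_minus_congruent"` (default; positive
#'   = larger on incongruent) or `"congruent_minus_incongruent"`.
#' @return A list of class `mm_score`: `mean_congruent_mm`,
#'   `mean_incongruent_mm`, `n_valid_congruent`, `n_valid_incongruent`,
#'   `difference_score_mm`, `included`.
#' @export
difference_score <- function(trial_results, min_trials = 5,
                             sign_convention = "incongruent_minus_congruent") {
  ok <- trial_results[trial_results$valid, , drop = FALSE]
  mc <- ok$window_mean_corrected_mm[ok$condition == "congruent"]
  mi <- ok$window_mean_corrected_mm[ok$condition == "incongruent"]
  included <- length(mc) >= min_trials && length(mi) >= min_trials
  diff <- if (!included) NA_real_ else if
    (sign_convention == "incongruent_minus_congruent") mean(mi) - mean(mc)
  else mean(mc) - mean(mi)
  structure(list(
    mean_congruent_mm = if (length(mc)) mean(mc) else NA_real_,
    mean_incongruent_mm = if (length(mi)) mean(mi) else NA_real_,
    n_valid_congruent = length(mc), n_valid_incongruent = length(mi),
    difference_score_mm = diff, included = included), class = "mm_score")
}

# Vectorised scoring of a participant-wave of mismatch trials stored as a
# trials x samples matrix of raw pupil values (plus the shared time grid).
# Identical in result to looping score_mm_trial over per-trial streams.
score_mm_matrix <- function(pupil, t_ms, design, geometry,
                            range_lo = 1.5, range_hi = 9, median_k = 14,
                            max_gap = 14, baseline_ms = 360, window_ms = 1200,
                            max_missing = 0.5, min_trials = 5,
                            sign_convention = "incongruent_minus_congruent") {
  stopifnot(nrow(pupil) == nrow(design), ncol(pupil) == length(t_ms))
  pupil[!is.na(pupil) & (pupil < range_lo | pupil > range_hi)] <- NA_real_
  res <- vector("list", nrow(design))
  bw <- mm_baseline_window(design[1, ], baseline_ms)
  aw <- mm_analysis_window(design[1, ], window_ms)
  inb <- t_ms >= bw["start"] & t_ms < bw["end"]
  inw <- t_ms >= aw["start"] & t_ms < aw["end"]
  sel <- inb | inw
  out <- data.frame(trial_index = design$trial_index,
                    condition = design$condition,
                    baseline_mean_mm = NA_real_,
                    window_mean_corrected_mm = NA_real_,
                    missing_fraction = NA_real_, valid = FALSE)
  for (i in seq_len(nrow(design))) {
    p <- .moving_median(pupil[i, ], as.integer(median_k))
    p <- fill_gaps_num(p, max_gap, inclusive = TRUE)
    miss <- mean(is.na(p[sel]))
    bvals <- p[inb]
    bmean <- if (any(!is.na(bvals))) mean(bvals, na.rm = TRUE) else NA_real_
    wvals <- p[inw] - bmean
    wm <- if (!is.na(bmean) && any(!is.na(wvals)))
      mean(wvals, na.rm = TRUE) else NA_real_
    out$baseline_mean_mm[i] <- bmean
    out$window_mean_corrected_mm[i] <- wm
    out$missing_fraction[i] <- miss
    out$valid[i] <- miss <= max_missing && !is.na(wm)
  }
  list(trials = out,
       score = difference_score(out, min_trials, sign_convention))
}
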