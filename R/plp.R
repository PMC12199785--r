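# Preferential-looking scoring: gap interpolation, analysis-window slicing,
# AOI looking times, bias-corrected pair scores, participant-level score.

# Linear interpolation of NA runs in a numeric vector. Runs flanked by
# observed values on both sides are filled when their length is < max_gap
# (inclusive = FALSE) or <= max_gap (inclusive = TRUE); edge runs never.
fill_gaps_num <- function(x, max_gap, inclusive = FALSE) {
  isna <- is.na(x)
  if (!any(isna)) return(x)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(x)
  for (j in which(r$values)) {
    len <- r$lengths[j]
    fill <- if (inclusive) len <= max_gap else len < max_gap
    lo <- starts[j] - 1L
    hi <- ends[j] + 1L
    if (fill && lo >= 1L && hi <= n) {
      x[starts[j]:ends[j]] <- x[lo] + (x[hi] - x[lo]) *
        (seq_len(len)) / (len + 1)
    }
  }
  x
}

#' Interpolate short gaze gaps
#'
#' Runs of invalid samples strictly shorter than `max_gap_samples` (default
#' 14 samples, about 117 ms at 120 Hz) that are flanked by valid samples are
#' filled by per-coordinate linear interpolation and marked valid. Longer
#' runs and runs touching the stream edges are left untouched, as are all
#' originally valid samples. Pupil values are not interpolated here (the
#' pupil pipeline has its own, inclusive, gap rule).
#'
#' @param stream A [sample_stream()].
#' @param max_gap_samples Gaps of this length or more are left open.
#' @return The interpolated [sample_stream()].
#' @export
interpolate_gaze_gaps <- function(stream, max_gap_samples = 14) {
  inval <- !stream$valid
  if (!any(inval)) return(stream)
  r <- rle(inval)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- nrow(stream)
  for (j in which(r$values)) {
    len <- r$lengths[j]
    lo <- starts[j] - 1L
    hi <- ends[j] + 1L
    if (len < max_gap_samples && lo >= 1L && hi <= n) {
      w <- seq_len(len) / (len + 1)
      idx <- starts[j]:ends[j]
      stream$x_px[idx] <- stream$x_px[lo] + (stream$x_px[hi] - stream$x_px[lo]) * w
      stream$y_px[idx] <- stream$y_px[lo] + (stream$y_px[hi] - stream$y_px[lo]) * w
      stream$valid[idx] <- TRUE
    }
  }
  stream
}

#' Slice a stream to the analysis window
#'
#' Keeps samples with `start_ms <= t < end_ms`. The default window (367 to
#' 2500 ms after picture onset) skips the time an infant needs to launch an
#' eye movement in response to the spoken label.
#'
#' @param stream A [sample_stream()].
#' @param start_ms,end_ms Window bounds on the trial clock, in ms.
#' @return The windowed [sample_stream()] (possibly empty).
#' @export
window_slice <- function(stream, start_ms = 367, end_ms = 2500) {
  out <- stream[stream$t_ms >= start_ms & stream$t_ms < end_ms, , drop = FALSE]
  attr(out, "geometry") <- stream_geometry(stream)
  class(out) <- class(stream)
  rownames(out) <- NULL
  out
}

#' Looking times within a windowed trial stream
#'
#' Classifies each valid on-screen sample into the target or distractor AOI
#' and converts sample counts to milliseconds. A trial is valid when the
#' fraction of valid on-screen gaze in the window is at least
#' `min_valid_fraction` (default 30%, about 640 ms of the 2133 ms window).
#'
#' @param stream_window Output of [window_slice()] after
#'   [interpolate_gaze_gaps()].
#' @param spec One row of a [gen_plp_design()] data.frame (needs
#'   `trial_index`, `pair_id`, `target_word`, `target_side`).
#' @param layout An [aoi_layout()].
#' @param geometry A [screen_geometry()]; defaults to the stream's.
#' @param min_valid_fraction Validity threshold on the window.
#' @return A one-row data.frame: `trial_index`, `pair_id`, `target_word`,
#'   `target_side`, `looking_target_ms`, `looking_distractor_ms`,
#'   `valid_ms`, `window_ms`, `valid`.
#' @export
trial_looking <- function(stream_window, spec, layout,
                          geometry = NULL, min_valid_fraction = 0.3) {
  if (is.null(geometry)) geometry <- stream_geometry(stream_window)
  period <- geometry$sample_period_ms
  n_win <- nrow(stream_window)
  onscreen <- stream_window$valid &
    !is.na(stream_window$x_px) & !is.na(stream_window$y_px) &
    stream_window$x_px >= 0 & stream_window$x_px < geometry$width_px &
    stream_window$y_px >= 0 & stream_window$y_px < geometry$height_px
  hits <- aoi_hit(stream_window$x_px, stream_window$y_px, layout, geometry)
  hits[!onscreen] <- "none"
  n_t <- sum(hits == spec$target_side)
  n_d <- sum(hits != "none" & hits != spec$target_side)
  n_valid <- sum(onscreen)
  data.frame(
    trial_index = spec$trial_index, pair_id = spec$pair_id,
    target_word = spec$target_word, target_side = spec$target_side,
    looking_target_ms = n_t * period, looking_distractor_ms = n_d * period,
    valid_ms = n_valid * period, window_ms = n_win * period,
    valid = n_win > 0 && n_valid / n_win >= min_valid_fraction,
    stringsAsFactors = FALSE)
}

#' Bias-corrected score for one picture pair
#'
#' For each picture X of the pair, the target-looking proportion when X was
#' the labelled target, minus the X-looking proportion when X served as
#' distractor; proportions use target + distractor AOI time as denominator,
#' and trials with zero AOI looking contribute no proportion. The pair score
#' is the mean over the (up to two) computable picture-level differences;
#' a pair with none is invalid (`NA`), not zero.
#'
#' @param results_for_pair Rows of [trial_looking()] results sharing one
#'   `pair_id` (invalid trials are ignored).
#' @return Pair score in `[-1, 1]`, or `NA` if not computable.
#' @export
pair_score <- function(results_for_pair) {
  res <- results_for_pair[results_for_pair$valid, , drop = FALSE]
  if (!nrow(res)) return(NA_real_)
  total <- res$looking_target_ms + res$looking_distractor_ms
  p_target <- ifelse(total > 0, res$looking_target_ms / total, NA_real_)
  pics <- unique(res$target_word)
  diffs <- numeric(0)
  for (pic in pics) {
    as_t <- p_target[res$target_word == pic]
    as_d <- 1 - p_target[res$target_word != pic]   # X-looking when X distracts
    as_t <- as_t[!is.na(as_t)]
    as_d <- as_d[!is.na(as_d)]
    if (length(as_t) && length(as_d))
      diffs <- c(diffs, mean(as_t) - mean(as_d))
  }
  if (!length(diffs)) NA_real_ else mean(diffs)
}

#' Participant-level preferential-looking score
#'
#' Scores each pair with [pair_score()] and averages the valid pair scores.
#' A participant is included only with valid data for at least `min_pairs`
#' of the pairs (default 4 of 8); excluded participants get a missing score
#' so that downstream imputation can handle them.
#'
#' @param trial_results Stacked [trial_looking()] rows for one participant.
#' @param min_pairs Minimum number of valid pairs for inclusion.
#' @return A list of class `plp_score`: `pair_scores` (named), `n_valid_pairs`,
#'   `participant_score`, `included`.
#' @export
participant_plp <- function(trial_results, min_pairs = 4) {
  test <- trial_results[!is.na(trial_results$pair_id), , drop = FALSE]
  pair_ids <- unique(test$pair_id)
  scores <- vapply(pair_ids, function(p)
    pair_score(test[test$pair_id == p, , drop = FALSE]), numeric(1))
  names(scores) <- pair_ids
  n_valid <- sum(!is.na(scores))
  included <- n_valid >= min_pairs
  structure(list(
    pair_scores = scores,
    n_valid_pairs = n_valid,
    participant_score = if (included) mean(scores, na.rm = TRUE) else NA_real_,
    included = included), class = "plp_score")
}

#' Mean total looking time per trial
#'
#' Mean of target + distractor AOI looking over valid trials, in seconds;
#' used by the exploratory attentiveness analysis.
#'
#' @param trial_results Stacked [trial_looking()] rows.
#' @return Seconds (scalar; `NA` with no valid trials).
#' @export
total_looking <- function(trial_results) {
  res <- trial_results[trial_results$valid, , drop = FALSE]
  if (!nrow(res)) return(NA_real_)
  mean(res$looking_target_ms + res$looking_distractor_ms) / 1000
}

# Vectorised scoring of a whole participant-wave of PLP trials held in long
# format (columns trial_index, t_ms, x_px, y_px, valid). Identical in result
# to looping trial_looking over per-trial streams; used by the pipeline and
# large simulations.
score_plp_long <- function(samples, design, layout, geometry,
                           window_start = 367, window_end = 2500,
                           max_gap = 14, min_valid_fraction = 0.3,
                           min_pairs = 4) {
  test <- design[design$kind == "test", , drop = FALSE]
  samples <- samples[samples$trial_index %in% test$trial_index, , drop = FALSE]
  if (any(!samples$valid)) {
    parts <- split(seq_len(nrow(samples)), samples$trial_index)
    for (idx in parts) {
      sub <- samples[idx, , drop = FALSE]
      inval <- !sub$valid
      if (!any(inval)) next
      sub$x_px[inval] <- NA_real_
      sub$y_px[inval] <- NA_real_
      x <- fill_gaps_num(sub$x_px, max_gap, inclusive = FALSE)
      y <- fill_gaps_num(sub$y_px, max_gap, inclusive = FALSE)
      newvalid <- sub$valid | (!is.na(x) & inval)
      samples$x_px[idx] <- x
      samples$y_px[idx] <- y
      samples$valid[idx] <- newvalid
    }
  }
  inwin <- samples$t_ms >= window_start & samples$t_ms < window_end
  samples <- samples[inwin, , drop = FALSE]
  onscreen <- samples$valid & !is.na(samples$x_px) & !is.na(samples$y_px) &
    samples$x_px >= 0 & samples$x_px < geometry$width_px &
    samples$y_px >= 0 & samples$y_px < geometry$height_px
  hits <- aoi_hit(samples$x_px, samples$y_px, layout, geometry)
  hits[!onscreen] <- "none"
  ti <- factor(samples$trial_index, levels = test$trial_index)
  period <- geometry$sample_period_ms
  n_win <- as.integer(table(ti))
  n_left <- as.integer(tapply((hits == "left") + 0, ti, sum, default = 0))
  n_right <- as.integer(tapply((hits == "right") + 0, ti, sum, default = 0))
  n_val <- as.integer(tapply(onscreen + 0, ti, sum, default = 0))
  is_left <- test$target_side == "left"
  n_t <- ifelse(is_left, n_left, n_right)
  n_d <- ifelse(is_left, n_right, n_left)
  data.frame(
    trial_index = test$trial_index, pair_id = test$pair_id,
    target_word = test$target_word, target_side = test$target_side,
    looking_target_ms = n_t * period, looking_distractor_ms = n_d * period,
    valid_ms = n_val * period, window_ms = n_win * period,
    valid = n_win > 0 & n_val / pmax(n_win, 1L) >= min_valid_fraction,
    stringsAsFactors = FALSE)
}
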