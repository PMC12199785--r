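# Shared fixtures: hand-built streams and brute-force oracles used as
# independent references for the vectorised implementations.

geom120 <- screen_geometry()
layout_default <- aoi_layout()

# a stream on the 120 Hz grid from plain vectors (t implied by index)
make_stream <- function(x = NULL, y = NULL, pupil = NULL, valid = NULL,
                        n = NULL, geometry = geom120) {
  if (is.null(n)) n <- max(length(x), length(y), length(pupil), length(valid))
  fill <- function(v, default) if (is.null(v)) rep(default, n) else v
  x <- fill(x, NA_real_); y <- fill(y, NA_real_)
  pupil <- fill(pupil, NA_real_)
  if (is.null(valid)) valid <- !is.na(x)
  t_ms <- (seq_len(n) - 1) * geometry$sample_period_ms
  sample_stream(t_ms, x, y, pupil, valid, geometry)
}

# centre coordinates of the two AOIs in pixels
aoi_centers <- function(layout = layout_default, geometry = geom120) {
  r <- aoi_rects(layout, geometry)
  list(left = c(mean(r$left[c("x0", "x1")]), mean(r$left[c("y0", "y1")])),
       right = c(mean(r$right[c("x0", "x1")]), mean(r$right[c("y0", "y1")])))
}

# brute-force NA-aware moving median (independent of the compiled filter):
# left-biased window for even k, truncated at edges
brute_moving_median <- function(x, k) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- max(1, i - k %/% 2)
    hi <- min(n, i + (k - 1) %/% 2)
    vals <- x[lo:hi]
    vals <- vals[!is.na(vals)]
    out[i] <- median(vals)
  }
  out
}

# a minimal single-trial mismatch spec on the button-press clock
mm_spec <- function(trial_index = 1, condition = "congruent") {
  data.frame(trial_index = trial_index, word = "word1",
             condition = condition, buttonpress_ms = 0,
             motion_onset_ms = 360, motion_offset_ms = 760,
             object_duration_ms = 1240, attention_getter_after = FALSE,
             stringsAsFactors = FALSE)
}

plp_test_spec <- function(trial_index = 5, pair_id = "pair1",
                          target_word = "pair1_a", target_side = "left") {
  data.frame(trial_index = trial_index, kind = "test", pair_id = pair_id,
             target_word = target_word, target_side = target_side,
             picture_onset_ms = 0, picture_duration_ms = 2500,
             sentence_offset_lead_ms = 250, attention_getter_after = FALSE,
             stringsAsFactors = FALSE)
}

# one trial_looking-style result row built directly
looking_row <- function(pair_id, target_word, target_side, target_ms,
                        distractor_ms, valid = TRUE, trial_index = 1) {
  data.frame(trial_index = trial_index, pair_id = pair_id,
             target_word = target_word, target_side = target_side,
             looking_target_ms = target_ms,
             looking_distractor_ms = distractor_ms,
             valid_ms = target_ms + distractor_ms, window_ms = 2125,
             valid = valid, stringsAsFactors = FALSE)
}
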