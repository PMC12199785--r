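# Pupil preprocessing and the congruency difference score.

test_that("the pupil keep-range is inclusive at 1.5 and 9 mm", {
  st <- make_stream(pupil = c(1.4, 1.5, 4, 9, 9.1), valid = rep(TRUE, 5),
                    x = rep(1, 5), y = rep(1, 5))
  out <- pupil_range_filter(st)
  expect_equal(is.na(out$pupil_left_mm), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$x_px, st$x_px)          # gaze untouched
  expect_identical(out$valid, st$valid)
})

test_that("moving median equals the brute-force sliding median with NAs", {
  set.seed(88)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    x <- rnorm(n, 4, 0.5)
    x[runif(n) < 0.2] <- NA
    for (k in c(3, 5, 14)) {
      st <- make_stream(pupil = x, valid = rep(TRUE, n),
                        x = rep(1, n), y = rep(1, n))
      expect_equal(median_filter(st, k)$pupil_left_mm,
                   brute_moving_median(x, k))
    }
  }
})

test_that("the median filter flattens single-sample spikes and keeps constants", {
  flat <- make_stream(pupil = rep(4, 60), valid = rep(TRUE, 60),
                      x = rep(1, 60), y = rep(1, 60))
  expect_equal(median_filter(flat)$pupil_left_mm, rep(4, 60))
  spike <- rep(4, 60); spike[30] <- 8
  sts <- make_stream(pupil = spike, valid = rep(TRUE, 60),
                     x = rep(1, 60), y = rep(1, 60))
  expect_equal(median_filter(sts)$pupil_left_mm, rep(4, 60))
})

test_that("pupil gaps up to 14 samples are filled, 15 are not (inclusive rule)", {
  gap14 <- make_stream(pupil = c(rep(3, 5), rep(NA, 14), rep(5, 5)),
                       valid = rep(TRUE, 24), x = rep(1, 24), y = rep(1, 24))
  out <- interpolate_pupil_gaps(gap14)
  expect_false(anyNA(out$pupil_left_mm))
  gap15 <- make_stream(pupil = c(rep(3, 5), rep(NA, 15), rep(5, 5)),
                       valid = rep(TRUE, 25), x = rep(1, 25), y = rep(1, 25))
  expect_equal(sum(is.na(interpolate_pupil_gaps(gap15)$pupil_left_mm)), 15)
  mid <- make_stream(pupil = c(3, NA, 5), valid = rep(TRUE, 3),
                     x = rep(1, 3), y = rep(1, 3))
  expect_equal(interpolate_pupil_gaps(mid)$pupil_left_mm, c(3, 4, 5))
})

test_that("baseline correction subtracts the pre-movement mean", {
  spec <- mm_spec()
  n <- 240
  st <- make_stream(pupil = rep(4, n), valid = rep(TRUE, n),
                    x = rep(1, n), y = rep(1, n))
  bc <- baseline_correct(st, spec)
  expect_equal(bc$baseline_mean_mm, 4)
  expect_equal(bc$stream$pupil_corrected_mm, rep(0, n))   # flat trace -> 0
  st2 <- st
  aw <- wordgaze:::mm_analysis_window(spec)
  st2$pupil_left_mm[st2$t_ms >= aw["start"]] <- 4.07
  bc2 <- baseline_correct(st2, spec)
  expect_equal(window_mean(bc2$stream, spec), 0.07)
  # baseline entirely missing -> invalid
  st3 <- st
  st3$pupil_left_mm[st3$t_ms < 360] <- NA
  expect_false(baseline_correct(st3, spec)$valid)
})

test_that("baseline-interval mean of every corrected trial is zero", {
  spec <- mm_spec()
  set.seed(14)
  for (i in 1:20) {
    p <- 4 + cumsum(rnorm(240, 0, 0.01))
    st <- make_stream(pupil = p, valid = rep(TRUE, 240),
                      x = rep(1, 240), y = rep(1, 240))
    bc <- baseline_correct(st, spec)
    inb <- st$t_ms >= 0 & st$t_ms < 360
    expect_lt(abs(mean(bc$stream$pupil_corrected_mm[inb])), 1e-9)
  }
})

test_that("the 1200 ms analysis window holds 144 samples at 120 Hz and averages correctly", {
  spec <- mm_spec()
  n <- 240
  aw <- wordgaze:::mm_analysis_window(spec)
  t_ms <- (seq_len(n) - 1) * geom120$sample_period_ms
  expect_equal(sum(t_ms >= aw["start"] & t_ms < aw["end"]), 144)
  corrected <- make_stream(pupil = rep(NA, n), valid = rep(TRUE, n),
                           x = rep(1, n), y = rep(1, n))
  corrected$pupil_corrected_mm <- rep(0.05, n)
  expect_equal(window_mean(corrected, spec), 0.05)
  half <- corrected
  inw <- t_ms >= aw["start"] & t_ms < aw["end"]
  vals <- rep(0, n); vals[inw][1:72] <- 0.1
  half$pupil_corrected_mm <- vals
  expect_equal(window_mean(half, spec), 0.05)
})

test_that("trial validity follows the more-than-50%-missing rule", {
  spec <- mm_spec()
  n <- 240
  t_ms <- (seq_len(n) - 1) * geom120$sample_period_ms
  aw <- wordgaze:::mm_analysis_window(spec)
  sel <- (t_ms >= 0 & t_ms < 360) | (t_ms >= aw["start"] & t_ms < aw["end"])
  n_sel <- sum(sel)   # 44 baseline + 144 window samples
  expect_equal(n_sel, 188)
  full <- make_stream(pupil = rep(4, n), valid = rep(TRUE, n),
                      x = rep(1, n), y = rep(1, n))
  expect_true(trial_validity_mm(full, spec))
  p60 <- rep(4, n)
  p60[which(sel)[seq_len(ceiling(0.6 * n_sel))]] <- NA
  st60 <- make_stream(pupil = p60, valid = rep(TRUE, n),
                      x = rep(1, n), y = rep(1, n))
  expect_false(trial_validity_mm(st60, spec))
  p50 <- rep(4, n)
  p50[which(sel)[seq_len(n_sel / 2)]] <- NA
  st50 <- make_stream(pupil = p50, valid = rep(TRUE, n),
                      x = rep(1, n), y = rep(1, n))
  expect_true(trial_validity_mm(st50, spec))     # exactly 50% is still valid
})

test_that("the difference score is incongruent minus congruent with the 5-trial rule", {
  mk <- function(cond, wm, valid = TRUE, idx = 1)
    data.frame(trial_index = idx, condition = cond, baseline_mean_mm = 4,
               window_mean_corrected_mm = wm, missing_fraction = 0,
               valid = valid)
  rows <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk("incongruent", 0.12, idx = i))),
    do.call(rbind, lapply(6:10, function(i) mk("congruent", 0.05, idx = i))))
  res <- difference_score(rows)
  expect_true(res$included)
  expect_equal(res$difference_score_mm, 0.07)
  # identical conditions -> 0
  same <- rows; same$window_mean_corrected_mm <- 0.1
  expect_equal(difference_score(same)$difference_score_mm, 0)
  # 4 valid congruent trials -> excluded, missing score
  rows4 <- rows; rows4$valid[6] <- FALSE
  res4 <- difference_score(rows4)
  expect_false(res4$included)
  expect_true(is.na(res4$difference_score_mm))
  # switchable convention
  expect_equal(difference_score(rows,
                 sign_convention = "congruent_minus_incongruent")$difference_score_mm,
               -0.07)
})

test_that("the preprocessing order is fixed; permuting median/interpolation changes spike-adjacent gaps", {
  spec <- mm_spec()
  p <- rep(4, 240)
  p[100:110] <- NA          # gap
  p[111] <- 6               # spike right after the gap
  st <- make_stream(pupil = p, valid = rep(TRUE, 240),
                    x = rep(1, 240), y = rep(1, 240))
  canonical <- interpolate_pupil_gaps(median_filter(pupil_range_filter(st)))
  res <- score_mm_trial(st, spec)
  bc <- baseline_correct(canonical, spec)
  expect_equal(res$window_mean_corrected_mm, window_mean(bc$stream, spec))
  permuted <- median_filter(interpolate_pupil_gaps(pupil_range_filter(st)))
  expect_false(isTRUE(all.equal(canonical$pupil_left_mm,
                                permuted$pupil_left_mm)))
})

test_that("right-eye data can never influence scores (left-eye only contract)", {
  # the sample schema carries only the left pupil; adding a rogue column
  # does not change any result
  spec <- mm_spec()
  st <- simulate_mm_trial(spec, 0.05, sim_config(gap_rate = 0), seed = 3)
  res1 <- score_mm_trial(st, spec)
  st$pupil_right_mm <- rev(st$pupil_left_mm)
  res2 <- score_mm_trial(st, spec)
  expect_equal(res1$window_mean_corrected_mm, res2$window_mean_corrected_mm)
})

test_that("matrix scoring matches the per-trial reference path", {
  cfg <- sim_config(gap_rate = 0.03, artifact_rate = 0.01)
  d <- gen_mm_design(seed = 4)
  set.seed(21)
  mat <- wordgaze:::simulate_mm_wave_matrix(d, 0.06, cfg, geom120)
  fast <- wordgaze:::score_mm_matrix(mat$pupil, mat$t_ms, d, geom120)
  slow <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    st <- sample_stream(mat$t_ms, rep(1, length(mat$t_ms)),
                        rep(1, length(mat$t_ms)), mat$pupil[i, ],
                        !is.na(mat$pupil[i, ]), geom120)
    score_mm_trial(st, d[i, ])
  }))
  expect_equal(fast$trials$window_mean_corrected_mm,
               slow$window_mean_corrected_mm)
  expect_equal(fast$trials$missing_fraction, slow$missing_fraction)
  expect_identical(fast$trials$valid, slow$valid)
  expect_equal(fast$score$difference_score_mm,
               difference_score(slow)$difference_score_mm)
})
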