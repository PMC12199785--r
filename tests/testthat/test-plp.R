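# Preferential-looking preprocessing and scoring.

test_that("gaze gaps shorter than the 14-sample limit are interpolated, longer ones kept", {
  cc <- aoi_centers()
  gap13 <- make_stream(x = c(rep(cc$left[1], 5), rep(NA, 13), rep(cc$left[1], 5)),
                       y = c(rep(cc$left[2], 5), rep(NA, 13), rep(cc$left[2], 5)))
  out <- interpolate_gaze_gaps(gap13)
  expect_true(all(out$valid))
  expect_equal(out$x_px, rep(cc$left[1], 23))     # constant endpoints fill flat
  gap14 <- make_stream(x = c(rep(100, 5), rep(NA, 14), rep(100, 5)),
                       y = c(rep(200, 5), rep(NA, 14), rep(200, 5)))
  out14 <- interpolate_gaze_gaps(gap14)
  expect_equal(sum(!out14$valid), 14)             # boundary: 14 stays open
})

test_that("interpolation is linear and never touches valid samples or edge gaps", {
  st <- make_stream(x = c(0, NA, NA, NA, 40, 50),
                    y = c(0, NA, NA, NA, 80, 90))
  out <- interpolate_gaze_gaps(st)
  expect_equal(out$x_px, c(0, 10, 20, 30, 40, 50))
  expect_equal(out$y_px, c(0, 20, 40, 60, 80, 90))
  # leading/trailing gaps are untouched even when short
  edge <- make_stream(x = c(NA, NA, 10, 20, NA), y = c(NA, NA, 1, 2, NA))
  oute <- interpolate_gaze_gaps(edge)
  expect_equal(sum(!oute$valid), 3)
  # property: originally valid samples unchanged on random streams
  set.seed(31)
  for (i in 1:20) {
    n <- 120
    valid <- runif(n) > 0.3
    st <- make_stream(x = ifelse(valid, runif(n, 0, 1920), NA),
                      y = ifelse(valid, runif(n, 0, 1080), NA), valid = valid)
    out <- interpolate_gaze_gaps(st)
    expect_equal(out$x_px[valid], st$x_px[valid])
    expect_equal(out$y_px[valid], st$y_px[valid])
    expect_true(all(out$valid[valid]))
  }
})

test_that("the analysis window keeps 367 <= t < 2500 and counts 255 samples at 120 Hz", {
  st <- make_stream(x = rep(1, 300), y = rep(1, 300))   # full 2500 ms trial
  win <- window_slice(st)
  # direct count: grid times k * 8.33ms, k = 45..299
  expect_equal(nrow(win), 255)
  expect_gte(min(win$t_ms), 367)
  expect_lt(max(win$t_ms), 2500)
  expect_equal(nrow(window_slice(st, 0, Inf)), 300)     # identity window
  short <- make_stream(x = rep(1, 40), y = rep(1, 40))  # ends before 367 ms
  expect_equal(nrow(window_slice(short)), 0)
})

test_that("looking times and the 30% validity rule are computed per trial", {
  cc <- aoi_centers()
  spec <- plp_test_spec(target_side = "left")
  n <- 255
  all_target <- make_stream(x = rep(cc$left[1], n), y = rep(cc$left[2], n))
  attr(all_target, "geometry") <- geom120
  res <- trial_looking(all_target, spec, layout_default)
  expect_equal(res$looking_target_ms, n * geom120$sample_period_ms)
  expect_equal(res$looking_distractor_ms, 0)
  expect_true(res$valid)

  # 20% valid gaze -> invalid trial
  nv <- round(0.2 * n)
  sparse <- make_stream(x = c(rep(cc$left[1], nv), rep(NA, n - nv)),
                        y = c(rep(cc$left[2], nv), rep(NA, n - nv)))
  expect_false(trial_looking(sparse, spec, layout_default)$valid)

  # half target AOI, half centre (no AOI): distractor 0, target half window
  half <- make_stream(x = c(rep(cc$left[1], 128), rep(960, 127)),
                      y = c(rep(cc$left[2], 128), rep(540, 127)))
  res2 <- trial_looking(half, spec, layout_default)
  expect_equal(res2$looking_target_ms, 128 * geom120$sample_period_ms)
  expect_equal(res2$looking_distractor_ms, 0)
  expect_true(res2$valid)   # centre looks still count as valid on-screen gaze
})

test_that("pair scores subtract distractor-role looking and respect bounds", {
  # picture a: 0.8 as target; picture b target trials give a 0.3 as distractor
  rows <- rbind(
    looking_row("p1", "p1_a", "left", 800, 200),   # a target, P = 0.8
    looking_row("p1", "p1_b", "right", 700, 300))  # b target, a looks = 0.3
  expect_equal(pair_score(rows), 0.5)
  # symmetric: b's difference is also (0.7 - 0.2) = 0.5 -> mean 0.5

  # perfect recognition
  perfect <- rbind(looking_row("p1", "p1_a", "left", 1000, 0),
                   looking_row("p1", "p1_b", "right", 1000, 0))
  expect_equal(pair_score(perfect), 1)

  # a pair with no computable role pairing is invalid, not zero
  onesided <- looking_row("p1", "p1_a", "left", 800, 200)
  expect_true(is.na(pair_score(onesided)))
  # zero-AOI trials contribute no proportion
  zero <- rbind(looking_row("p1", "p1_a", "left", 0, 0),
                looking_row("p1", "p1_b", "right", 600, 400))
  expect_true(is.na(pair_score(zero)))
})

test_that("pair score is antisymmetric under swapping target/distractor roles", {
  set.seed(55)
  for (i in 1:20) {
    t1 <- runif(2, 100, 1000); d1 <- runif(2, 100, 1000)
    rows <- rbind(looking_row("p", "p_a", "left", t1[1], d1[1]),
                  looking_row("p", "p_b", "right", t1[2], d1[2]))
    swapped <- rows
    swapped$target_word <- rev(rows$target_word)
    tmp <- swapped$looking_target_ms
    swapped$looking_target_ms <- swapped$looking_distractor_ms
    swapped$looking_distractor_ms <- tmp
    expect_equal(pair_score(swapped), -pair_score(rows), tolerance = 1e-12)
  }
})

test_that("label-insensitive gaze with a fixed picture bias scores zero in expectation", {
  # gaze follows picture attractiveness only: picture a draws 70% regardless
  # of which picture is labelled
  rows <- rbind(
    looking_row("p1", "p1_a", "left", 700, 300),
    looking_row("p1", "p1_a", "right", 700, 300),
    looking_row("p1", "p1_b", "left", 300, 700),
    looking_row("p1", "p1_b", "right", 300, 700))
  expect_equal(pair_score(rows), 0)
})

test_that("participant score averages valid pairs and applies the 4-of-8 rule", {
  mk <- function(pair, score_frac) {
    # a pair whose score is exactly 2*score_frac - 1 ... construct directly
    rbind(looking_row(pair, paste0(pair, "_a"), "left", 1000 * score_frac,
                      1000 * (1 - score_frac)),
          looking_row(pair, paste0(pair, "_b"), "right", 1000 * score_frac,
                      1000 * (1 - score_frac)))
  }
  # three valid pairs only -> excluded
  rows3 <- rbind(mk("p1", 0.6), mk("p2", 0.7), mk("p3", 0.5),
                 looking_row("p4", "p4_a", "left", 500, 500, valid = FALSE))
  res3 <- participant_plp(rows3)
  expect_equal(res3$n_valid_pairs, 3)
  expect_false(res3$included)
  expect_true(is.na(res3$participant_score))
  # mean of pair scores
  scores <- c(0.2, -0.2, 0.1, 0.3)
  rows4 <- do.call(rbind, lapply(seq_along(scores), function(i)
    mk(paste0("p", i), (scores[i] + 1) / 2)))
  res4 <- participant_plp(rows4)
  expect_true(res4$included)
  expect_equal(res4$participant_score, 0.1, tolerance = 1e-12)
  expect_true(abs(res4$participant_score) <= 1)
})

test_that("total looking averages AOI time over valid trials in seconds", {
  rows <- rbind(looking_row("p1", "p1_a", "left", 2133, 0),
                looking_row("p1", "p1_b", "right", 1000, 1133))
  expect_equal(total_looking(rows), 2.133)
  none <- looking_row("p1", "p1_a", "left", 0, 0)
  expect_equal(total_looking(none), 0)
})

test_that("vectorised participant scoring matches the per-trial reference path", {
  cfg <- sim_config(gap_rate = 0.03, gap_mean_len = 8)
  d <- gen_plp_design(seed = 9)
  set.seed(123)
  long <- wordgaze:::simulate_plp_wave_long(d, 0.1, cfg, geom120,
                                            layout_default, wave = 1)
  fast <- wordgaze:::score_plp_long(long, d, layout_default, geom120)
  test <- d[d$kind == "test", ]
  slow <- do.call(rbind, lapply(seq_len(nrow(test)), function(i) {
    idx <- long$trial_index == test$trial_index[i]
    st <- sample_stream(long$t_ms[idx], long$x_px[idx], long$y_px[idx],
                        rep(NA_real_, sum(idx)), long$valid[idx], geom120)
    st <- interpolate_gaze_gaps(st)
    trial_looking(window_slice(st), test[i, ], layout_default)
  }))
  expect_equal(fast$looking_target_ms, slow$looking_target_ms)
  expect_equal(fast$looking_distractor_ms, slow$looking_distractor_ms)
  expect_equal(fast$valid_ms, slow$valid_ms)
  expect_identical(fast$valid, slow$valid)
})
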