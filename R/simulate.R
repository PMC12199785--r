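# Synthetic-cohort generator. Produces complete studies -- trial designs,
# gaze/pupil sample streams, CDI-style vocabulary tables, covariates, and
# missingness -- with known ground truth, so every downstream stage can be
# tested without any real recordings.

#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic study. Defaults describe a
#' 70-child longitudinal cohort assessed at 10, 11.5, 18 and 24 months:
#' the preferential-looking task at the first three waves, the pupillometric
#' mismatch task at the first two, and parent-reported vocabulary at all
#' four.
#'
#' Gaze micro-model: within a trial the eye alternates between fixations
#' with exponential dwell times; each fixation lands off-AOI with
#' probability `p_away` (wave-specific, shaping total looking time),
#' otherwise on the target with probability
#' `0.5 + preference + (bias_target - bias_distractor)`. Pupil micro-model:
#' participant baseline plus slow linear drift plus an event-evoked
#' dilation starting at occluder motion offset, whose sample-grid mean over
#' the analysis window equals the trial's true amplitude, plus white
#' measurement noise, blink gaps and rare out-of-range artifacts.
#'
#' @param n_participants Cohort size.
#' @param seed Optional integer seed stored with the config.
#' @param plp_effect Slope of the target preference on latent ability
#'   (probability units per SD).
#' @param plp_mean_pref Population mean target preference.
#' @param picture_bias_sd SD of per-picture attractiveness biases.
#' @param dwell_mean_ms Mean fixation dwell time.
#' @param p_away_plp Per-PLP-wave probability that a fixation lands outside
#'   both AOIs (attention to the stimuli grows with age).
#' @param plp_offscreen_share Share of away fixations that leave the screen
#'   entirely (and therefore do not count as valid on-screen gaze).
#' @param mm_effect_mm Per-MM-wave group-mean congruency effect in mm
#'   (signed; the default flips sign between waves to emulate the observed
#'   developmental reversal).
#' @param mm_ability_slope Per-MM-wave slope of the congruency effect on
#'   latent ability (mm per SD).
#' @param pupil_base_mm,pupil_base_sd Participant pupil baseline mean/SD.
#' @param pupil_trial_sd Trial-to-trial baseline SD.
#' @param pupil_drift_sd SD of the per-trial linear drift slope (mm/s).
#' @param pupil_event_amp Condition-independent event dilation amplitude.
#' @param pupil_noise_sd Per-sample measurement noise SD (mm).
#' @param event_tau_ms Rise time constant of the event response.
#' @param artifact_rate Per-sample probability of an out-of-range spike.
#' @param gap_rate Per-sample blink/track-loss hazard.
#' @param gap_mean_len Geometric mean gap length in samples.
#' @param cdi_comp_logit,cdi_prod_logit Per-wave logits of the expected
#'   comprehension/production fraction of the 90-item checklist.
#' @param cdi_ability_slope Latent-ability slope on the CDI logit scale.
#' @param cdi_noise_sd Wave-level CDI noise on the logit scale.
#' @param missing_prob Measure-level missingness rates: list with `cdi`
#'   (scalar), `plp` (length 3), `mm` (length 2).
#' @param missing_mode `"MCAR"` (default) or `"MAR"` (missingness then
#'   depends on latent ability, for MCAR-test power checks).
#' @param mar_strength Logit shift per SD of ability under MAR.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 70, seed = NULL,
                       plp_effect = 0.15, plp_mean_pref = 0.03,
                       picture_bias_sd = 0.05,
                       dwell_mean_ms = 400,
                       p_away_plp = c(0.30, 0.22, 0.08),
                       plp_offscreen_share = 0.4,
                       mm_effect_mm = c(-0.05, 0.05),
                       mm_ability_slope = c(0.02, -0.05),
                       pupil_base_mm = 4, pupil_base_sd = 0.3,
                       pupil_trial_sd = 0.1, pupil_drift_sd = 0.1,
                       pupil_event_amp = 0.1, pupil_noise_sd = 0.05,
                       event_tau_ms = 75, artifact_rate = 0.001,
                       gap_rate = 0.07, gap_mean_len = 12,
                       cdi_comp_logit = c(-1.15, -0.31, 1.33, 3.07),
                       cdi_prod_logit = c(-4.5, -3.37, -1.22, 1.65),
                       cdi_ability_slope = 0.8, cdi_noise_sd = 0.6,
                       missing_prob = list(cdi = 0.05,
                                           plp = c(0.10, 0.10, 0.03),
                                           mm = c(0.17, 0.17)),
                       missing_mode = c("MCAR", "MAR"),
                       mar_strength = 1.5) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(n_participants = as.integer(n_participants), seed = seed,
              plp_effect = plp_effect, plp_mean_pref = plp_mean_pref,
              picture_bias_sd = picture_bias_sd,
              dwell_mean_ms = dwell_mean_ms, p_away_plp = p_away_plp,
              plp_offscreen_share = plp_offscreen_share,
              mm_effect_mm = mm_effect_mm,
              mm_ability_slope = mm_ability_slope,
              pupil_base_mm = pupil_base_mm, pupil_base_sd = pupil_base_sd,
              pupil_trial_sd = pupil_trial_sd,
              pupil_drift_sd = pupil_drift_sd,
              pupil_event_amp = pupil_event_amp,
              pupil_noise_sd = pupil_noise_sd,
              event_tau_ms = event_tau_ms, artifact_rate = artifact_rate,
              gap_rate = gap_rate, gap_mean_len = gap_mean_len,
              cdi_comp_logit = cdi_comp_logit,
              cdi_prod_logit = cdi_prod_logit,
              cdi_ability_slope = cdi_ability_slope,
              cdi_noise_sd = cdi_noise_sd,
              missing_prob = missing_prob, missing_mode = missing_mode,
              mar_strength = mar_strength,
              wave_ages = c(10, 11.5, 18, 24))
  probs <- c(unlist(missing_prob), gap_rate, artifact_rate, p_away_plp,
             plp_offscreen_share)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_participants < 2) stop("n_participants must be >= 2")
  if (length(p_away_plp) != 3 || length(mm_effect_mm) != 2 ||
      length(mm_ability_slope) != 2)
    stop("p_away_plp needs 3 waves; mm_effect_mm / mm_ability_slope need 2")
  class(cfg) <- "sim_config"
  cfg
}

# blink/track-loss gap mask: TRUE where the signal is lost
gap_mask <- function(n, gap_rate, gap_mean_len) {
  lost <- rep(FALSE, n)
  if (gap_rate <= 0) return(lost)
  starts <- which(runif(n) < gap_rate)
  if (!length(starts)) return(lost)
  lens <- rgeom(length(starts), 1 / gap_mean_len) + 1L
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(n, starts[i] + lens[i] - 1L)
    lost[idx] <- TRUE
  }
  lost
}

# core gaze generator: plain vectors for speed (no data.frame overhead)
sim_plp_trial_core <- function(n_samples, period, p_target, p_away,
                               dwell_mean_ms, rects, target_side,
                               gap_rate, gap_mean_len, jitter_px = 15,
                               offscreen_share = 0) {
  t_grid <- (seq_len(n_samples) - 1) * period
  total <- n_samples * period
  nfix <- max(4L, ceiling(total / dwell_mean_ms * 3) + 4L)
  dwell <- pmax(rexp(nfix, 1 / dwell_mean_ms), 80)
  while (sum(dwell) < total) dwell <- c(dwell, pmax(rexp(4, 1 / dwell_mean_ms), 80))
  fix_of_sample <- findInterval(t_grid, cumsum(dwell)) + 1L
  nfix <- max(fix_of_sample)
  away <- runif(nfix) < p_away
  offscreen <- away & runif(nfix) < offscreen_share
  on_target <- runif(nfix) < p_target
  cx <- ifelse(away, (rects$left[["x1"]] + rects$right[["x0"]]) / 2,
               ifelse(on_target,
                      if (target_side == "left")
                        mean(rects$left[c("x0", "x1")]) else
                          mean(rects$right[c("x0", "x1")]),
                      if (target_side == "left")
                        mean(rects$right[c("x0", "x1")]) else
                          mean(rects$left[c("x0", "x1")])))
  cy <- rep(mean(rects$left[c("y0", "y1")]), nfix)
  fx <- cx + rnorm(nfix, 0, jitter_px)
  fy <- cy + rnorm(nfix, 0, jitter_px)
  fx[offscreen] <- -100
  fy[offscreen] <- -100
  x <- fx[fix_of_sample]
  y <- fy[fix_of_sample]
  lost <- gap_mask(n_samples, gap_rate, gap_mean_len)
  x[lost] <- NA_real_
  y[lost] <- NA_real_
  list(t_ms = t_grid, x_px = x, y_px = y, valid = !lost)
}

#' Simulate one preferential-looking trial
#'
#' Generates a 2500 ms gaze stream at the configured sampling rate using the
#' two-state fixation model. The expected proportion of AOI looking directed
#' at the target is `0.5 + preference + (bias_target - bias_distractor)`.
#'
#' @param spec One row of a [gen_plp_design()] data.frame.
#' @param preference Participant's true target preference.
#' @param cfg A [sim_config()].
#' @param geometry,layout Screen geometry and AOI layout.
#' @param wave PLP wave index 1-3 (selects `p_away_plp`).
#' @param bias_target,bias_distractor Picture attractiveness biases.
#' @param seed Optional seed.
#' @return A [sample_stream()] (pupil channel all missing).
#' @export
simulate_plp_trial <- function(spec, preference, cfg = sim_config(),
                               geometry = screen_geometry(),
                               layout = aoi_layout(), wave = 1,
                               bias_target = 0, bias_distractor = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  period <- geometry$sample_period_ms
  n <- as.integer(round(spec$picture_duration_ms / period))
  p_t <- min(max(0.5 + preference + bias_target - bias_distractor, 0.02), 0.98)
  core <- sim_plp_trial_core(n, period, p_t, cfg$p_away_plp[wave],
                             cfg$dwell_mean_ms, aoi_rects(layout, geometry),
                             spec$target_side, cfg$gap_rate, cfg$gap_mean_len,
                             offscreen_share = cfg$plp_offscreen_share)
  sample_stream(core$t_ms, core$x_px, core$y_px,
                rep(NA_real_, n), core$valid, geometry)
}

# event-response kernel, normalized so that its mean over the analysis
# window sample grid is exactly 1 (amplitude is then recoverable as the
# corrected window mean)
mm_kernel <- function(t_ms, onset_ms, tau_ms, window_sel) {
  k <- ifelse(t_ms > onset_ms, 1 - exp(-(t_ms - onset_ms) / tau_ms), 0)
  m <- mean(k[window_sel])
  if (m > 0) k / m else k
}

sim_mm_trial_core <- function(t_ms, spec, delta, cfg, window_sel) {
  n <- length(t_ms)
  base <- cfg$pupil_base_mm + rnorm(1, 0, cfg$pupil_trial_sd)
  drift <- rnorm(1, 0, cfg$pupil_drift_sd) * t_ms / 1000
  amp <- cfg$pupil_event_amp +
    if (spec$condition == "incongruent") delta else 0
  k <- mm_kernel(t_ms, spec$motion_offset_ms, cfg$event_tau_ms, window_sel)
  p <- base + drift + amp * k + rnorm(n, 0, cfg$pupil_noise_sd)
  spikes <- runif(n) < cfg$artifact_rate
  p[spikes] <- sample(c(0.8, 9.8), sum(spikes), replace = TRUE)
  p[gap_mask(n, cfg$gap_rate, cfg$gap_mean_len)] <- NA_real_
  p
}

#' Simulate one mismatch trial's pupil stream
#'
#' Pupil trace on the button-press clock covering the baseline, occluder
#' motion, and analysis window: participant/trial baseline plus slow drift
#' plus an event-evoked dilation after motion offset with amplitude
#' `pupil_event_amp + delta` on incongruent trials (and `pupil_event_amp`
#' on congruent ones), white noise, blink gaps and rare out-of-range
#' artifacts.
#'
#' @param spec One row of a [gen_mm_design()] data.frame.
#' @param delta Participant's true congruency effect in mm.
#' @param cfg A [sim_config()].
#' @param geometry Screen/recording geometry.
#' @param participant_base Optional participant baseline in mm (defaults to
#'   `pupil_base_mm`).
#' @param seed Optional seed.
#' @return A [sample_stream()] (gaze channels held at screen centre).
#' @export
simulate_mm_trial <- function(spec, delta, cfg = sim_config(),
                              geometry = screen_geometry(),
                              participant_base = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  period <- geometry$sample_period_ms
  dur <- spec$motion_offset_ms + 1240
  n <- as.integer(ceiling(dur / period))
  t_ms <- (seq_len(n) - 1) * period
  aw <- mm_analysis_window(spec)
  window_sel <- t_ms >= aw["start"] & t_ms < aw["end"]
  cfg2 <- cfg
  if (!is.null(participant_base)) cfg2$pupil_base_mm <- participant_base
  p <- sim_mm_trial_core(t_ms, spec, delta, cfg2, window_sel)
  valid <- !is.na(p)
  sample_stream(t_ms, rep(geometry$width_px / 2, n),
                rep(geometry$height_px / 2, n), p, valid, geometry)
}

#' Generate the synthetic participant table and its ground truth
#'
#' Draws latent ability, covariates and four waves of CDI comprehension and
#' production scores (integers in 0-90, growing towards ceiling), then
#' injects measure-level missingness at the configured rates (MCAR by
#' default, ability-dependent under `missing_mode = "MAR"`). Eye-tracking
#' scores are not filled in here; the pipeline computes them from simulated
#' streams and merges them into the same table.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return A list: `table` (data.frame, one row per participant) and
#'   `truth` (latent abilities, true preferences, true congruency effects,
#'   per-wave expected CDI fractions).
#' @export
gen_participant_table <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  ability <- rnorm(n)
  gender <- rbinom(n, 1, 0.5)
  parent_university <- rbinom(n, 1, 0.70)
  monolingual_swedish <- rbinom(n, 1, 0.757)
  family_history <- rbinom(n, 1, 0.157)
  read_lat <- 0.2 * ability + rnorm(n)
  reading_freq <- findInterval(pnorm(read_lat), c(0.05, 0.25, 0.60))
  reading_dur <- findInterval(pnorm(0.6 * read_lat + 0.8 * rnorm(n)),
                              c(0.15, 0.50, 0.80))
  bayley_scaled <- pmin(pmax(round(10 + 1.2 * ability + 2 * rnorm(n)), 1), 19)
  tab <- data.frame(id = sprintf("p%03d", seq_len(n)),
                    ability = ability, gender = gender,
                    parent_university = parent_university,
                    monolingual_swedish = monolingual_swedish,
                    family_history = family_history,
                    reading_freq = reading_freq,
                    reading_duration = reading_dur,
                    bayley_scaled = bayley_scaled,
                    stringsAsFactors = FALSE)
  tab$reading_composite <- as.numeric(
    reading_composite(tab$reading_freq, tab$reading_duration))
  wave_suffix <- c("10", "11_5", "18", "24")
  for (w in 1:4) {
    for (meas in c("comp", "prod")) {
      logit <- cfg[[paste0("cdi_", meas, "_logit")]][w]
      eta <- logit + cfg$cdi_ability_slope * ability +
        rnorm(n, 0, cfg$cdi_noise_sd)
      tab[[paste0(meas, "_", wave_suffix[w])]] <-
        pmin(pmax(as.integer(round(90 * plogis(eta))), 0L), 90L)
    }
  }
  # measure-level missingness on the CDI columns
  for (w in 1:4) for (meas in c("comp", "prod")) {
    col <- paste0(meas, "_", wave_suffix[w])
    pmiss <- miss_prob_vec(cfg$missing_prob$cdi, ability, cfg)
    tab[[col]][runif(n) < pmiss] <- NA_integer_
  }
  truth <- list(ability = ability,
                preference = cfg$plp_mean_pref + cfg$plp_effect * ability,
                mm_delta = sapply(1:2, function(w)
                  cfg$mm_effect_mm[w] + cfg$mm_ability_slope[w] * ability),
                cdi_comp_expected = sapply(1:4, function(w)
                  plogis(cfg$cdi_comp_logit[w] +
                           cfg$cdi_ability_slope * ability)),
                cdi_prod_expected = sapply(1:4, function(w)
                  plogis(cfg$cdi_prod_logit[w] +
                           cfg$cdi_ability_slope * ability)))
  list(table = tab, truth = truth)
}

miss_prob_vec <- function(rate, ability, cfg) {
  if (rate <= 0) return(rep(0, length(ability)))
  if (cfg$missing_mode == "MCAR") return(rep(rate, length(ability)))
  plogis(qlogis(rate) - cfg$mar_strength * ability)
}

# Long-format simulation of all test trials of one PLP participant-wave;
# used by the pipeline and large property checks.
simulate_plp_wave_long <- function(design, preference, cfg, geometry, layout,
                                   wave = 1, picture_bias = NULL) {
  test <- design[design$kind == "test", , drop = FALSE]
  period <- geometry$sample_period_ms
  n <- as.integer(round(test$picture_duration_ms[1] / period))
  rects <- aoi_rects(layout, geometry)
  if (is.null(picture_bias)) {
    pics <- unique(test$target_word)
    picture_bias <- setNames(rep(0, length(pics)), pics)
  }
  out <- vector("list", nrow(test))
  for (i in seq_len(nrow(test))) {
    sp <- test[i, ]
    pair_pics <- names(picture_bias)[startsWith(names(picture_bias),
                                                paste0(sp$pair_id, "_"))]
    b_t <- picture_bias[[sp$target_word]]
    other <- setdiff(pair_pics, sp$target_word)
    b_d <- if (length(other)) picture_bias[[other]] else 0
    p_t <- min(max(0.5 + preference + b_t - b_d, 0.02), 0.98)
    core <- sim_plp_trial_core(n, period, p_t, cfg$p_away_plp[wave],
                               cfg$dwell_mean_ms, rects, sp$target_side,
                               cfg$gap_rate, cfg$gap_mean_len,
                               offscreen_share = cfg$plp_offscreen_share)
    out[[i]] <- core
  }
  data.frame(trial_index = rep(test$trial_index, each = n),
             t_ms = unlist(lapply(out, `[[`, "t_ms")),
             x_px = unlist(lapply(out, `[[`, "x_px")),
             y_px = unlist(lapply(out, `[[`, "y_px")),
             valid = unlist(lapply(out, `[[`, "valid")))
}

# Matrix-format simulation of one MM participant-wave (trials x samples).
simulate_mm_wave_matrix <- function(design, delta, cfg, geometry,
                                    participant_base = NULL) {
  period <- geometry$sample_period_ms
  dur <- design$motion_offset_ms[1] + 1240
  nsamp <- as.integer(ceiling(dur / period))
  t_ms <- (seq_len(nsamp) - 1) * period
  aw <- mm_analysis_window(design[1, ])
  wsel <- t_ms >= aw["start"] & t_ms < aw["end"]
  cfg2 <- cfg
  if (!is.null(participant_base)) cfg2$pupil_base_mm <- participant_base
  pupil <- matrix(NA_real_, nrow(design), nsamp)
  for (i in seq_len(nrow(design)))
    pupil[i, ] <- sim_mm_trial_core(t_ms, design[i, ], delta, cfg2, wsel)
  list(pupil = pupil, t_ms = t_ms)
}
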