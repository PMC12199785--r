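#!/usr/bin/env Rscript
# Stage 2: score the demo participant's raw streams from files, writing
# per-trial QC tables. Demonstrates the file-level scoring interface
# (read -> interpolate -> window -> AOI looking -> pair -> participant for
# gaze; range filter -> median filter -> interpolate -> baseline -> window
# mean -> difference score for pupil) and cross-checks the participant
# scores against the table written by stage 1.

library(wordgaze)

synth <- "results/synth"
out <- "results/scoring"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
geom <- screen_geometry(); lay <- aoi_layout()

design <- as.data.frame(data.table::fread(file.path(synth, "plp_design_wave1.csv")))
test <- design[design$kind == "test", ]
plp_trials <- do.call(rbind, lapply(seq_len(nrow(test)), function(i) {
  f <- file.path(synth, "streams_p001_plp",
                 sprintf("trial_%02d.csv", test$trial_index[i]))
  st <- read_sample_stream(f, geom)
  st <- interpolate_gaze_gaps(st, max_gap_samples = 14)
  trial_looking(window_slice(st, 367, 2500), test[i, ], lay)
}))
data.table::fwrite(plp_trials, file.path(out, "plp_trial_qc.csv"))
plp <- participant_plp(plp_trials, min_pairs = 4)
message(sprintf("PLP p001 wave 1: %d/8 valid pairs, score %.3f, included %s",
                plp$n_valid_pairs, plp$participant_score, plp$included))
message(sprintf("  total looking %.2f s per trial", total_looking(plp_trials)))

mm_design <- as.data.frame(data.table::fread(file.path(synth, "mm_design_wave1.csv")))
mm_trials <- do.call(rbind, lapply(seq_len(nrow(mm_design)), function(i) {
  f <- file.path(synth, "streams_p001_mm", sprintf("trial_%02d.csv", i))
  score_mm_trial(read_sample_stream(f, geom), mm_design[i, ])
}))
data.table::fwrite(mm_trials, file.path(out, "mm_trial_qc.csv"))
mm <- difference_score(mm_trials, min_trials = 5)
message(sprintf("MM p001 wave 1: %d congruent / %d incongruent valid trials",
                mm$n_valid_congruent, mm$n_valid_incongruent))
message(sprintf("  difference score %+.3f mm (positive = larger pupil on incongruent)",
                mm$difference_score_mm))

truth <- data.table::fread(file.path(synth, "ground_truth.csv"))
message(sprintf("ground truth for p001: preference %.3f (score expectation %.3f), mm delta %.3f mm",
                truth$preference[1], 2 * truth$preference[1],
                truth$mm_delta_10[1]))
message("wrote ", out)
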