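#!/usr/bin/env Rscript
# Stage 1: generate the synthetic longitudinal cohort.
#
# Produces, under results/synth/:
#   - the pseudorandomized trial designs for both eye-tracking tasks,
#   - the scored participant table (CDI, covariates, preferential-looking
#     and mismatch scores per wave, with missingness),
#   - the generator's ground truth (latent abilities, true effects),
#   - raw sample streams for one demo participant-wave, as the CSV format
#     the scoring stage reads.

library(wordgaze)

seed <- 20260930
out <- "results/synth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(NULL, seed = seed)
message(sprintf("simulated %d participants", nrow(cohort$scores)))

data.table::fwrite(cohort$scores, file.path(out, "participant_scores.csv"))
data.table::fwrite(cohort$designs$plp[[1]], file.path(out, "plp_design_wave1.csv"))
data.table::fwrite(cohort$designs$mm[[1]], file.path(out, "mm_design_wave1.csv"))
saveRDS <- NULL  # (no binary outputs: ground truth goes to CSV)
truth <- data.frame(id = cohort$scores$id,
                    ability = cohort$truth$ability,
                    preference = cohort$truth$preference,
                    mm_delta_10 = cohort$truth$mm_delta[, 1],
                    mm_delta_11_5 = cohort$truth$mm_delta[, 2])
data.table::fwrite(truth, file.path(out, "ground_truth.csv"))

# demo raw streams: participant 1, wave 1, both tasks
geom <- screen_geometry(); lay <- aoi_layout()
sim <- sim_config()
design <- cohort$designs$plp[[1]]
set.seed(seed + 1)
long <- wordgaze:::simulate_plp_wave_long(design, cohort$truth$preference[1],
                                          sim, geom, lay, wave = 1,
                                          picture_bias = cohort$truth$picture_bias)
dir.create(file.path(out, "streams_p001_plp"), showWarnings = FALSE)
for (ti in unique(long$trial_index)) {
  sub <- long[long$trial_index == ti, ]
  st <- sample_stream(sub$t_ms, sub$x_px, sub$y_px,
                      rep(NA_real_, nrow(sub)), sub$valid, geom)
  write_sample_stream(st, file.path(out, "streams_p001_plp",
                                    sprintf("trial_%02d.csv", ti)))
}
mm_design <- cohort$designs$mm[[1]]
set.seed(seed + 2)
mat <- wordgaze:::simulate_mm_wave_matrix(mm_design,
                                          cohort$truth$mm_delta[1, 1], sim,
                                          geom)
dir.create(file.path(out, "streams_p001_mm"), showWarnings = FALSE)
for (i in seq_len(nrow(mm_design))) {
  st <- sample_stream(mat$t_ms, rep(geom$width_px / 2, length(mat$t_ms)),
                      rep(geom$height_px / 2, length(mat$t_ms)),
                      mat$pupil[i, ], !is.na(mat$pupil[i, ]), geom)
  write_sample_stream(st, file.path(out, "streams_p001_mm",
                                    sprintf("trial_%02d.csv", i)))
}

message("eye-tracking inclusion after scoring:")
for (nm in names(cohort$qc))
  message(sprintf("  %-8s mean valid trials %5.1f, included %d, technical loss %d",
                  nm, cohort$qc[[nm]]$mean_valid_trials,
                  cohort$qc[[nm]]$n_included, cohort$qc[[nm]]$n_technical_loss))
message("wrote ", out)
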