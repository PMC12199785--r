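#!/usr/bin/env Rscript
# Stage 4: figures summarizing the synthetic study -- CDI growth curves,
# an example baseline-corrected pupil trace by condition, and the
# zero-order correlation matrix -- written under results/figures/.

library(wordgaze)
library(ggplot2)

out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tab <- as.data.frame(data.table::fread("results/synth/participant_scores.csv"))

## CDI growth with ceiling at 90
waves <- c("10" = 10, "11_5" = 11.5, "18" = 18, "24" = 24)
cdi <- do.call(rbind, lapply(names(waves), function(w)
  rbind(data.frame(age = waves[[w]], measure = "comprehension",
                   score = tab[[paste0("comp_", w)]]),
        data.frame(age = waves[[w]], measure = "production",
                   score = tab[[paste0("prod_", w)]]))))
p1 <- ggplot(cdi, aes(factor(age), score, fill = measure)) +
  geom_boxplot(outlier.size = 0.5) +
  geom_hline(yintercept = 90, linetype = 2) +
  labs(x = "age (months)", y = "CDI score (0-90)",
       title = "Parent-reported vocabulary growth (synthetic cohort)") +
  theme_minimal()
ggsave(file.path(out, "cdi_growth.png"), p1, width = 7, height = 4, dpi = 150)

## example pupil traces: mean corrected dilation by condition
geom <- screen_geometry()
sim <- sim_config(gap_rate = 0, artifact_rate = 0)
design <- gen_mm_design(seed = 42)
set.seed(42)
mat <- wordgaze:::simulate_mm_wave_matrix(design, 0.07, sim, geom)
corrected <- t(apply(mat$pupil, 1, function(p) {
  st <- sample_stream(mat$t_ms, rep(1, length(p)), rep(1, length(p)), p,
                      !is.na(p), geom)
  bc <- baseline_correct(median_filter(pupil_range_filter(st)), design[1, ])
  bc$stream$pupil_corrected_mm
}))
tr <- data.frame(
  t_ms = rep(mat$t_ms, 2),
  condition = rep(c("congruent", "incongruent"), each = length(mat$t_ms)),
  mean_mm = c(colMeans(corrected[design$condition == "congruent", ]),
              colMeans(corrected[design$condition == "incongruent", ])))
p2 <- ggplot(tr, aes(t_ms, mean_mm, colour = condition)) +
  geom_line() +
  geom_vline(xintercept = c(360, 760, 1960), linetype = 3) +
  annotate("text", x = c(180, 560, 1360), y = max(tr$mean_mm),
           label = c("baseline", "occluder", "analysis window"), size = 3) +
  labs(x = "time from button press (ms)", y = "corrected pupil (mm)",
       title = "Mean baseline-corrected pupil response (true effect +0.07 mm)") +
  theme_minimal()
ggsave(file.path(out, "pupil_trace.png"), p2, width = 7, height = 4, dpi = 150)

## correlation heatmap from stage 3
rho <- as.matrix(data.table::fread("results/stats/cor_zero_rho.csv"),
                 rownames = 1)
hm <- data.frame(row = rep(rownames(rho), ncol(rho)),
                 col = rep(colnames(rho), each = nrow(rho)),
                 rho = as.vector(rho))
hm$row <- factor(hm$row, levels = rev(rownames(rho)))
hm$col <- factor(hm$col, levels = colnames(rho))
p3 <- ggplot(hm, aes(col, row, fill = rho)) +
  geom_tile() +
  scale_fill_gradient2(limits = c(-1, 1)) +
  labs(x = NULL, y = NULL, title = "Zero-order Spearman correlations") +
  theme_minimal() +
  theme(axis.text.x = element_text(angle = 45, hjust = 1))
ggsave(file.path(out, "correlations.png"), p3, width = 7, height = 6, dpi = 150)

message("wrote ", out)
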