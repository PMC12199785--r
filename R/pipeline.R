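# End-to-end orchestration: synthetic cohort -> trial scoring -> missing
# data handling -> correlation analyses -> report bundle.

derive_seeds <- function(seed, n = 6) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

outcome_vars <- function() {
  c("comp_10", "prod_10", "comp_11_5", "prod_11_5", "comp_18", "prod_18",
    "comp_24", "prod_24", "plp_10", "plp_11_5", "plp_18", "mm_10", "mm_11_5")
}

outcome_labels <- function() {
  c("Com 10 months", "Pro 10 months", "Com 11.5 months", "Pro 11.5 months",
    "Com 18 months", "Pro 18 months", "Com 24 months", "Pro 24 months",
    "PLP 10 months", "PLP 11.5 months", "PLP 18 months",
    "MM 10 months", "MM 11.5 months")
}

covariate_vars <- function() {
  c("gender", "parent_university", "monolingual_swedish", "family_history",
    "reading_composite", "bayley_scaled")
}

#' Simulate and score a full synthetic cohort
#'
#' Generates the participant table, simulates and scores every
#' preferential-looking participant-wave (waves at 10, 11.5 and 18 months)
#' and every mismatch participant-wave (10 and 11.5 months), and applies
#' measure-level technical-loss missingness. All randomness derives from
#' `seed`.
#'
#' @param config Pipeline configuration (see [validate_config()]).
#' @param seed Integer seed.
#' @return A list: `scores` (participant table with outcome columns),
#'   `truth`, `qc` (per-wave counters), `designs`.
#' @export
simulate_cohort <- function(config = NULL, seed = 1) {
  cfg <- validate_config(config)
  sim <- do.call(sim_config, cfg$sim)
  geometry <- do.call(screen_geometry, cfg$geometry)
  layout <- do.call(aoi_layout, cfg$aoi)
  a <- cfg$analysis
  seeds <- derive_seeds(seed, 6)

  set.seed(seeds[1])
  plp_designs <- lapply(1:3, function(w)
    gen_plp_design(cfg$design$n_pairs, cfg$design$reps_per_picture,
                   strict_side = cfg$design$strict_side))
  mm_designs <- lapply(1:2, function(w)
    gen_mm_design(cfg$design$n_words, cfg$design$reps_per_condition))
  pics <- unique(plp_designs[[1]]$target_word[plp_designs[[1]]$kind == "test"])
  picture_bias <- setNames(rnorm(length(pics), 0, sim$picture_bias_sd), pics)

  set.seed(seeds[2])
  pt <- gen_participant_table(sim)
  tab <- pt$table
  truth <- pt$truth
  truth$picture_bias <- picture_bias
  n <- nrow(tab)
  qc <- list()

  set.seed(seeds[3])
  for (w in 1:3) {
    design <- plp_designs[[w]]
    score <- rep(NA_real_, n)
    look <- rep(NA_real_, n)
    nvalid <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      long <- simulate_plp_wave_long(design, truth$preference[i], sim,
                                     geometry, layout, wave = w,
                                     picture_bias = picture_bias)
      trials <- score_plp_long(long, design, layout, geometry,
                               a$plp_window_start_ms, a$plp_window_end_ms,
                               a$gaze_max_gap_samples,
                               a$plp_min_valid_fraction, a$plp_min_pairs)
      ps <- participant_plp(trials, a$plp_min_pairs)
      score[i] <- ps$participant_score
      look[i] <- total_looking(trials)
      nvalid[i] <- sum(trials$valid)
    }
    lost <- runif(n) < sim$missing_prob$plp[w]
    score[lost] <- NA_real_
    look[lost] <- NA_real_
    suff <- c("10", "11_5", "18")[w]
    tab[[paste0("plp_", suff)]] <- score
    tab[[paste0("plp_look_", suff)]] <- look
    qc[[paste0("plp_", suff)]] <- list(
      mean_valid_trials = mean(nvalid), n_technical_loss = sum(lost),
      n_included = sum(!is.na(score)))
  }

  set.seed(seeds[4])
  for (w in 1:2) {
    design <- mm_designs[[w]]
    score <- rep(NA_real_, n)
    nv <- matrix(NA_integer_, n, 2)
    for (i in seq_len(n)) {
      base_i <- sim$pupil_base_mm + rnorm(1, 0, sim$pupil_base_sd)
      mat <- simulate_mm_wave_matrix(design, truth$mm_delta[i, w], sim,
                                     geometry, participant_base = base_i)
      res <- score_mm_matrix(mat$pupil, mat$t_ms, design, geometry,
                             a$pupil_range_mm[1], a$pupil_range_mm[2],
                             a$pupil_median_k, a$pupil_max_gap_samples,
                             a$mm_baseline_ms, a$mm_window_ms,
                             a$mm_max_missing, a$mm_min_trials,
                             a$mm_sign_convention)
      score[i] <- res$score$difference_score_mm
      nv[i, ] <- c(res$score$n_valid_congruent, res$score$n_valid_incongruent)
    }
    lost <- runif(n) < sim$missing_prob$mm[w]
    score[lost] <- NA_real_
    suff <- c("10", "11_5")[w]
    tab[[paste0("mm_", suff)]] <- score
    qc[[paste0("mm_", suff)]] <- list(
      mean_valid_trials = mean(rowSums(nv)), n_technical_loss = sum(lost),
      n_included = sum(!is.na(score)))
  }

  list(scores = tab, truth = truth, qc = qc,
       designs = list(plp = plp_designs, mm = mm_designs))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates cohort simulation, scoring, Little's MCAR test, EM
#' imputation, descriptives, zero-order and covariate-controlled Spearman
#' correlation matrices, the sensitivity analysis, and the exploratory
#' attentiveness summary; optionally writes the report bundle as CSV/JSON
#' files plus a run manifest.
#'
#' @param config Pipeline configuration (see [validate_config()]).
#' @param seed Integer seed driving all randomness.
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `wordgaze_run`: `scores`, `truth`, `qc`,
#'   `mcar`, `em`, `descriptives`, `cor_zero`, `cor_partial`,
#'   `sensitivity`, `attentiveness`, `manifest`.
#' @export
run_all <- function(config = NULL, seed = 1, out_dir = NULL) {
  cfg <- validate_config(config)
  cohort <- simulate_cohort(cfg, seed)
  tab <- cohort$scores
  vars <- outcome_vars()
  labels <- outcome_labels()
  outcomes <- tab[vars]

  mcar <- tryCatch(little_mcar(outcomes),
                   error = function(e) list(message = conditionMessage(e)))
  em <- em_impute(outcomes)
  imputed <- cbind(tab[setdiff(names(tab), vars)], em$imputed)

  desc <- do.call(rbind, lapply(seq_along(vars), function(i)
    descriptives(em$imputed[[vars[i]]], labels[i])))

  cor_zero <- correlation_report(imputed, vars, NULL, labels)
  cor_partial <- correlation_report(imputed, vars, covariate_vars(), labels)

  sens <- list(n = nrow(tab), alpha = 0.05, power = 0.80, tails = 2,
               r_exact = min_detectable_r(nrow(tab), 0.05, 0.80, 2, "exact"),
               r_fisher = min_detectable_r(nrow(tab), 0.05, 0.80, 2, "fisher-z"))

  look_cols <- paste0("plp_look_", c("10", "11_5", "18"))
  look_means <- colMeans(tab[look_cols], na.rm = TRUE)
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  att_tests <- lapply(pairs, function(pr) {
    res <- paired_t(tab[[look_cols[pr[1]]]], tab[[look_cols[pr[2]]]])
    c(wave_a = pr[1], wave_b = pr[2], t = res$t, df = res$df, p = res$p)
  })
  mm_group <- c(mm_10 = mean(tab$mm_10, na.rm = TRUE),
                mm_11_5 = mean(tab$mm_11_5, na.rm = TRUE))
  attentiveness <- list(total_looking_s = look_means,
                        paired_tests = do.call(rbind, att_tests),
                        mm_group_means_mm = mm_group)

  run <- list(scores = tab, truth = cohort$truth, qc = cohort$qc,
              mcar = mcar, em = em, descriptives = desc,
              cor_zero = cor_zero, cor_partial = cor_partial,
              sensitivity = sens, attentiveness = attentiveness,
              manifest = NULL)
  run$manifest <- build_manifest(cfg, seed)
  class(run) <- "wordgaze_run"
  if (!is.null(out_dir)) write_run(run, out_dir, cfg, seed)
  run
}

build_manifest <- function(cfg, seed, files = character(0)) {
  list(package = "wordgaze",
       version = as.character(utils::packageVersion("wordgaze")),
       seed = seed,
       config = unclass(cfg),
       outputs = if (length(files))
         as.list(tools::md5sum(files)) else list())
}

write_run <- function(run, out_dir, cfg, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(df, path)
    path
  }
  files <- c(
    w(run$scores, "participant_scores.csv"),
    w(run$descriptives, "descriptives.csv"),
    w(as.data.frame(run$cor_zero$rho), "cor_zero_rho.csv"),
    w(as.data.frame(run$cor_zero$p), "cor_zero_p.csv"),
    w(as.data.frame(run$cor_partial$rho), "cor_partial_rho.csv"),
    w(as.data.frame(run$cor_partial$p), "cor_partial_p.csv"))
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  print(run)
  sink()
  close(con)
  files <- c(files, summary_path)
  run$manifest <- build_manifest(cfg, seed, files)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' @export
print.wordgaze_run <- function(x, ...) {
  cat("wordgaze pipeline run\n")
  cat(sprintf("participants: %d; seed: %s\n", nrow(x$scores),
              format(x$manifest$seed)))
  if (!is.null(x$mcar$d2))
    cat(sprintf("Little's MCAR: d2 = %.1f, df = %d, p = %.3f\n",
                x$mcar$d2, x$mcar$df, x$mcar$p))
  cat(sprintf("EM imputation: %d iterations, converged: %s\n",
              x$em$iterations, x$em$converged))
  cat("\nDescriptives (after imputation):\n")
  print(transform(x$descriptives,
                  median = round(median, 2), sd = round(sd, 2),
                  skewness = round(skewness, 2),
                  kurtosis = round(kurtosis, 2)), row.names = FALSE)
  cat(sprintf("\nSensitivity: minimum detectable |rho| = %.4f (exact), %.4f (Fisher-z)\n",
              x$sensitivity$r_exact, x$sensitivity$r_fisher))
  cat(sprintf("Total looking (s) at 10 / 11.5 / 18 months: %s\n",
              paste(round(x$attentiveness$total_looking_s, 2), collapse = " / ")))
  cat(sprintf("MM group means (mm) at 10 / 11.5 months: %s\n",
              paste(round(x$attentiveness$mm_group_means_mm, 3), collapse = " / ")))
  invisible(x)
}
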