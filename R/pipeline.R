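## End-to-end pipeline arms: simulate -> extract -> robustness-filter ->
## select -> fit -> evaluate, with reproducible seeded configuration.

#' Pipeline run configuration
#'
#' Bundles every tunable of the simulation and analysis: cohort sizes, the
#' phantom spec template, discretization/texture settings, CCC thresholds,
#' test-retest perturbation, and the master seed from which every cohort
#' seed is derived. The configuration hash is stamped into outputs.
#'
#' @param seed Master integer seed.
#' @param n_train,n_validation,n_retest Cohort sizes (default 20 each).
#' @param heterogeneity_gain,noise_sigma,base_suv Phantom parameters (see
#'   [phantom_spec()]).
#' @param n_levels Discretization levels.
#' @param ccc_threshold_pet,ccc_threshold_ct Robustness cutoffs.
#' @param perturbation Test-retest perturbation (see
#'   [generate_test_retest_pair()]): repositioning shift, per-session
#'   lognormal intensity rescale, independent noise.
#' @param out_dir Optional output directory; when set, the arms write model
#'   JSON, feature CSVs, the robustness report and metric JSON there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 42L, n_train = 20L, n_validation = 20L,
                       n_retest = 20L, heterogeneity_gain = 1,
                       noise_sigma = 0.05, base_suv = 2, n_levels = 64L,
                       ccc_threshold_pet = 0.65, ccc_threshold_ct = 0.75,
                       perturbation = list(shift_mm = c(1.2, -0.9, 0.7),
                                           intensity_scale_sd = 0.15,
                                           noise_seed_offset = 1L),
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_train = as.integer(n_train),
              n_validation = as.integer(n_validation),
              n_retest = as.integer(n_retest),
              heterogeneity_gain = heterogeneity_gain,
              noise_sigma = noise_sigma, base_suv = base_suv,
              n_levels = as.integer(n_levels),
              ccc_threshold_pet = ccc_threshold_pet,
              ccc_threshold_ct = ccc_threshold_ct,
              perturbation = perturbation, out_dir = out_dir)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> seed %d, n = %d/%d/%d (train/validation/retest), gain %.2g, noise %.2g, hash %s\n",
    x$seed, x$n_train, x$n_validation, x$n_retest, x$heterogeneity_gain,
    x$noise_sigma, x$hash))
  invisible(x)
}

cfg_spec_template <- function(config) {
  phantom_spec(heterogeneity_gain = config$heterogeneity_gain,
               noise_sigma = config$noise_sigma, base_suv = config$base_suv)
}

# Test-retest cohort: per-subject paired scans sharing the latent lesion.
generate_retest_cohort <- function(n, timecourse, day, spec_template,
                                   seed, perturbation, jitter_frac = 0.08) {
  if (!is_count(n) || n < 4) stopf("cohort size n must be an integer >= 4")
  days <- rep_len(as.integer(day), n)
  test <- vector("list", n); retest <- vector("list", n)
  for (i in seq_len(n)) {
    st <- sample_exhaustion_state(timecourse, days[i], derive_seed(seed, i))
    jit <- with_seed(derive_seed(seed, 2000L + i),
                     stats::runif(3, 1 - jitter_frac, 1 + jitter_frac))
    sp <- spec_template
    sp$tumor_semi_axes_mm <- sp$tumor_semi_axes_mm * jit
    sp$seed <- derive_seed(seed, 1000L + i)
    pair <- generate_test_retest_pair(sp, st, perturbation)
    pair$test$pet$meta$subject_id <- pair$test$ct$meta$subject_id <- sprintf("S%03d", i)
    pair$retest$pet$meta$subject_id <- pair$retest$ct$meta$subject_id <- sprintf("S%03d", i)
    test[[i]] <- pair$test; retest[[i]] <- pair$retest
  }
  list(test = test, retest = retest)
}

# Rank robust features by how many characteristic selections picked them;
# fall back to the canonical texture/kurtosis triple to fill open slots.
choose_score_triple <- function(selection, catalog_order) {
  picked <- unlist(lapply(selection, function(s) s$feature), use.names = FALSE)
  if (length(picked)) {
    tab <- table(factor(picked, levels = catalog_order))
    tab <- tab[tab > 0]
    ranked <- names(tab)[order(-as.numeric(tab), match(names(tab), catalog_order))]
  } else ranked <- character(0)
  triple <- utils::head(ranked, 3)
  if (length(triple) < 3) {
    triple <- c(triple, setdiff(.canonical_triple, triple))[1:3]
  }
  triple
}

#' Run the training arm
#'
#' Executes the full training pipeline on synthetic surrogates of the
#' checkpoint-inhibitor cohorts: a mixed LLC-like + B16-like cohort spanning
#' pre/post-ICI days 0, 7 and 22 (so exhaustion levels range from
#' reinvigorated to heavily exhausted), a paired test-retest cohort for the
#' CCC robustness filter, LASSO selection of exhaustion-correlated PET
#' features, an unpenalized three-feature logistic refit, and training-set
#' evaluation (C-index, Brier score, calibration).
#'
#' @param config A [run_config()].
#' @return A list of class `training_result` with elements `model`
#'   ([texscore()]), `selection`, `robustness`, `score_features`, `features`,
#'   `truth`, `metrics`, `config`.
#' @export
run_training_arm <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  tmpl <- cfg_spec_template(config)
  n_half <- config$n_train %/% 2
  llc <- generate_cohort(n_half, llc_ici_timecourse(), c(0L, 7L, 22L),
                         tmpl, seed = derive_seed(config$seed, 1L))
  b16 <- generate_cohort(config$n_train - n_half, b16_ici_timecourse(),
                         c(0L, 7L, 22L), tmpl, seed = derive_seed(config$seed, 2L))
  cohort <- combine_cohorts(llc, b16)
  feats <- extract_cohort_features(cohort, "pet",
                                   discretization_config(config$n_levels))

  rt <- generate_retest_cohort(config$n_retest, llc_rt_timecourse(),
                               c(0L, 3L, 7L, 14L, 21L), tmpl,
                               seed = derive_seed(config$seed, 3L),
                               perturbation = config$perturbation)
  rob <- filter_features(
    extract_cohort_features(rt$test, "pet", discretization_config(config$n_levels)),
    extract_cohort_features(rt$retest, "pet", discretization_config(config$n_levels)),
    "pet", threshold = config$ccc_threshold_pet)

  robust <- retained_features(rob)
  if (length(robust) < 3) stopf("robustness filter retained only %d features", length(robust))
  sel <- select_exhaustion_features(feats[, c("subject_id", robust)],
                                    cohort$ground_truth)
  triple <- choose_score_triple(sel, robust)
  model <- texscore(feats, cohort$ground_truth$terminal_tex_frac, triple)
  ev <- evaluate_texscore(model, feats, cohort$ground_truth$label_high)
  metrics <- list(arm = "training", n = config$n_train,
                  c_index = ev$c_index, brier = ev$brier,
                  config_hash = config$hash)
  res <- structure(list(model = model, selection = sel, robustness = rob,
                        score_features = triple, features = feats,
                        truth = cohort$ground_truth,
                        metrics = metrics, calibration = ev$calibration,
                        config = config),
                   class = "training_result")
  if (!is.null(config$out_dir)) write_arm_outputs(res, config$out_dir, "training")
  res
}

#' Run the validation arm
#'
#' Applies a frozen model to an independently seeded synthetic surrogate of
#' the irradiation cohort: LLC-like post-RT subjects spanning days 0-21, so
#' terminal exhaustion covers baseline, peak and post-peak levels. Reports
#' C-index, Brier score, calibration and the high-exhaustion call rate
#' against the validation cohort's own median-split label.
#'
#' @param config A [run_config()].
#' @param model A `texscore` model (refit or packaged).
#' @return A list of class `validation_result`.
#' @export
run_validation_arm <- function(config, model) {
  stopifnot(inherits(config, "run_config"), inherits(model, "texscore"))
  tmpl <- cfg_spec_template(config)
  cohort <- generate_cohort(config$n_validation, llc_rt_timecourse(),
                            c(0L, 3L, 7L, 14L, 21L), tmpl,
                            seed = derive_seed(config$seed, 4L))
  feats <- extract_cohort_features(cohort, "pet",
                                   discretization_config(config$n_levels))
  miss <- setdiff(model$feature_names, colnames(feats))
  if (length(miss)) stopf("model/catalog mismatch: features %s absent from the %s catalog",
                          paste(miss, collapse = ", "), attr(feats, "catalog_id"))
  ev <- evaluate_texscore(model, feats, cohort$ground_truth$label_high)
  metrics <- list(arm = "validation", n = config$n_validation,
                  c_index = ev$c_index, brier = ev$brier,
                  call_rate = mean(ev$probability > 0.5),
                  config_hash = config$hash)
  res <- structure(list(features = feats, truth = cohort$ground_truth,
                        probability = ev$probability, metrics = metrics,
                        calibration = ev$calibration, config = config),
                   class = "validation_result")
  if (!is.null(config$out_dir)) write_arm_outputs(res, config$out_dir, "validation")
  res
}

write_arm_outputs <- function(res, dir, arm) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- res$features
  feats$config_hash <- res$config$hash
  utils::write.csv(feats, file.path(dir, sprintf("%s_features.csv", arm)),
                   row.names = FALSE)
  utils::write.csv(res$truth, file.path(dir, sprintf("%s_ground_truth.csv", arm)),
                   row.names = FALSE)
  jsonlite::write_json(res$metrics, file.path(dir, sprintf("%s_metrics.json", arm)),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$calibration, file.path(dir, sprintf("%s_calibration.csv", arm)),
                   row.names = FALSE)
  if (arm == "training") {
    write_texscore(res$model, file.path(dir, "model.json"))
    utils::write.csv(as.data.frame(res$robustness),
                     file.path(dir, "robustness_report.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf("<training_result> n = %d, C-index %.3f, Brier %.3f\n",
              x$metrics$n, x$metrics$c_index, x$metrics$brier))
  cat("  score features:", paste(x$score_features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> n = %d, C-index %.3f, Brier %.3f, call rate %.2f\n",
              x$metrics$n, x$metrics$c_index, x$metrics$brier,
              x$metrics$call_rate))
  invisible(x)
}
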