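#' Validate and normalize a run configuration
#'
#' Configurations are JSON key trees. Missing keys fall back to defaults that
#' mirror the study design: five dataset roles (SiMoA 145/559, Elecsys
#' 169/525, their fusion, a first-trimester subset 65/190, an independent
#' test set 130/892), 24 calibration pairs under 100 rounds of 3-fold CV,
#' a random forest with output threshold 0.5, and desk-scale repeated CV
#' (10 rounds of 10 folds; the paper-scale 100 rounds is a config change).
#' An empty file or `NULL` yields the all-defaults configuration with
#' seed 0.
#'
#' @param config path to a JSON file, a named list, or `NULL` for defaults.
#' @return a normalized list of class `perisk_run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  }
  config <- config %||% list()
  defaults <- list(
    seed = 0L, out_dir = ".",
    cohorts = list(
      simoa = list(n_cases = 145L, n_controls = 559L, platform_mix = 1.0),
      elecsys = list(n_cases = 169L, n_controls = 525L, platform_mix = 0.0),
      first_trimester = list(n_cases = 65L, n_controls = 190L,
                             platform_mix = 1.0,
                             gestational_day_range = c(77L, 97L)),
      test = list(n_cases = 130L, n_controls = 892L, platform_mix = 1.0)),
    calibration = list(n_pairs = 24L, rounds = 100L, folds = 3L),
    pipeline = list(algorithm = "rf", hyperparameters = list(),
                    threshold = 0.5, early_threshold = 0.21,
                    rounds = 10L, folds = 10L, grid = 0.01,
                    stratified = FALSE),
    augmentation = list(method = "kmeans_smote", target_ratio = 1.2,
                        k_neighbors = 5L))
  cfg <- utils::modifyList(defaults, as.list(config))

  errors <- character(0)
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(cfg$pipeline$threshold > 0 && cfg$pipeline$threshold < 1,
      "pipeline.threshold must lie strictly inside (0, 1)")
  chk(cfg$pipeline$early_threshold > 0 && cfg$pipeline$early_threshold < 1,
      "pipeline.early_threshold must lie strictly inside (0, 1)")
  chk(cfg$pipeline$rounds >= 1, "pipeline.rounds must be >= 1")
  chk(cfg$pipeline$folds >= 2, "pipeline.folds must be >= 2")
  chk(cfg$pipeline$grid > 0 && cfg$pipeline$grid <= 0.5,
      "pipeline.grid must lie in (0, 0.5]")
  chk(cfg$pipeline$algorithm %in% c("rf", "mlp", "svm", "xgb", "ada"),
      "pipeline.algorithm must be one of rf/mlp/svm/xgb/ada")
  chk(cfg$calibration$n_pairs >= 3, "calibration.n_pairs must be >= 3")
  chk(cfg$calibration$rounds >= 1, "calibration.rounds must be >= 1")
  chk(cfg$augmentation$target_ratio > 0, "augmentation.target_ratio must be positive")
  for (role in names(cfg$cohorts)) {
    cc <- cfg$cohorts[[role]]
    chk((cc$n_cases %||% 1) >= 1, sprintf("cohorts.%s.n_cases must be >= 1", role))
    chk((cc$n_controls %||% 1) >= 1, sprintf("cohorts.%s.n_controls must be >= 1", role))
    mr <- cc$missing_rate %||% 0.25
    chk(mr >= 0 && mr < 1, sprintf("cohorts.%s.missing_rate must lie in [0, 1)", role))
  }
  if (length(errors))
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  class(cfg) <- "perisk_run_config"
  cfg
}

EXPERIMENTS <- c("model_comparison", "bi_platform_fusion", "threshold_search",
                 "early_prediction", "augmentation_study")

cohort_from_config <- function(cfg, role) {
  cc <- cfg$cohorts[[role]]
  args <- cc[names(cc) %in% names(formals(cohort_spec))]
  args$seed <- derive_seed(cfg$seed, paste("cohort", role))
  generate_cohort(do.call(cohort_spec, args))
}

predictor_from_config <- function(cfg, threshold = cfg$pipeline$threshold) {
  predictor_config(cfg$pipeline$algorithm, cfg$pipeline$hyperparameters,
                   seed = derive_seed(cfg$seed, "predictor"),
                   threshold = threshold)
}

# build the bi-platform fusion table: SiMoA rows plus Elecsys rows with PlGF
# mapped onto the reference scale by the fitted calibration model
build_fusion <- function(cfg) {
  simoa <- cohort_from_config(cfg, "simoa")
  elecsys <- cohort_from_config(cfg, "elecsys")
  pairs <- generate_calibration_set(
    cfg$calibration$n_pairs,
    transfer_params = attr(simoa, "spec")$transfer_params,
    seed = derive_seed(cfg$seed, "calibration pairs"))
  cal <- fit_calibrators(pairs, rounds = cfg$calibration$rounds,
                         folds = cfg$calibration$folds,
                         seed = derive_seed(cfg$seed, "calibration"))
  fused <- rbind(as.data.frame(simoa), as.data.frame(elecsys))
  class(fused) <- c("perisk_cohort", "data.frame")
  fused <- calibrate_cohort(fused, cal)
  list(simoa = simoa, elecsys = elecsys, fused = fused, calibration = cal)
}

fmt_cell <- function(s) sprintf("%.4f ± %.4f", s$median, s$deviation)

summary_row <- function(res, keys = c("error_rate", "tpr", "fpr", "auc_roc",
                                      "auc_prc", "f1")) {
  vapply(keys, function(k) fmt_cell(res$summary[[k]]), "")
}

#' Run one of the five built-in experiments
#'
#' Regenerates a study-shaped experiment end-to-end on synthetic cohorts:
#' `model_comparison` (five algorithms on the SiMoA set),
#' `bi_platform_fusion` (mono-platform vs. calibrated fusion, default and
#' searched thresholds), `threshold_search` (F1-optimal output threshold),
#' `early_prediction` (first-trimester CV vs. non-early enrichment) and
#' `augmentation_study` (real vs. real+augmented training with real-only test
#' partitions). Each experiment writes `<name>.json` (full resolved config,
#' seed and per-round metrics) and `<name>.txt` (an aligned median +/-
#' deviation table) under `out_dir` and is deterministic under the master
#' seed.
#'
#' @param name experiment name, one of
#'   `r paste0('\x60', EXPERIMENTS, '\x60', collapse = ", ")`.
#' @param config a [validate_config()] result (or anything it accepts).
#' @param out_dir output directory; defaults to the config's.
#' @param dry_run list the planned stages without computing.
#' @param verbose emit stage-by-stage messages.
#' @return the report list, invisibly (visibly for `dry_run`).
#' @export
run_experiment <- function(name, config = NULL, out_dir = NULL,
                           dry_run = FALSE, verbose = FALSE) {
  if (!name %in% EXPERIMENTS)
    stopf("unknown experiment '%s'; choose one of: %s", name,
          paste(EXPERIMENTS, collapse = ", "))
  cfg <- if (inherits(config, "perisk_run_config")) config else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  say <- function(stage) if (verbose) message("[", name, "] ", stage)

  stages <- switch(name,
    model_comparison = c("generate simoa cohort", "repeated CV per algorithm", "report"),
    bi_platform_fusion = c("generate cohorts", "fit calibration", "CV mono and fusion",
                           "threshold search", "report"),
    threshold_search = c("generate cohorts", "fit calibration", "grid search", "report"),
    early_prediction = c("generate cohorts", "fit calibration", "early-only CV",
                         "early-enriched CV", "report"),
    augmentation_study = c("generate elecsys cohort", "real-only CV",
                           "augmented CV with real-only test", "report"))
  if (dry_run) return(list(experiment = name, stages = stages))

  pl <- cfg$pipeline
  report <- switch(name,
    model_comparison = {
      say("generate simoa cohort")
      simoa <- cohort_from_config(cfg, "simoa")
      rows <- lapply(c("mlp", "svm", "rf", "xgb", "ada"), function(alg) {
        say(paste("repeated CV:", alg))
        res <- repeated_cv(simoa, predictor_config(alg, seed = derive_seed(cfg$seed, alg)),
                           rounds = pl$rounds, folds = pl$folds,
                           threshold = pl$threshold, seed = cfg$seed,
                           stratified = pl$stratified)
        c(algorithm = alg,
          setNames(as.list(summary_row(res, c("error_rate", "f1", "auc_roc"))),
                   c("error_rate", "f1", "auc_roc")),
          micro_f1 = sprintf("%.4f", res$summary$micro_f1),
          macro_f1 = sprintf("%.4f", res$summary$macro_f1))
      })
      list(table = do.call(rbind, lapply(rows, as.data.frame)))
    },
    bi_platform_fusion = {
      say("generate cohorts + calibration")
      sets <- build_fusion(cfg)
      cvs <- list(
        Simoa_Results = repeated_cv(sets$simoa, predictor_from_config(cfg),
                                    pl$rounds, pl$folds, pl$threshold, cfg$seed),
        Elecsys_Results = repeated_cv(sets$elecsys, predictor_from_config(cfg),
                                      pl$rounds, pl$folds, pl$threshold, cfg$seed),
        Simoa_Elecsys_Results_t0.5 = repeated_cv(sets$fused, predictor_from_config(cfg),
                                                 pl$rounds, pl$folds, pl$threshold, cfg$seed))
      say("threshold search")
      ts <- optimize_threshold(sets$fused, predictor_from_config(cfg),
                               rounds = max(2L, pl$rounds %/% 2L),
                               folds = pl$folds, grid = pl$grid, seed = cfg$seed)
      cvs$Simoa_Elecsys_Results_opt <- repeated_cv(
        sets$fused, predictor_from_config(cfg, threshold = ts$median),
        pl$rounds, pl$folds, ts$median, cfg$seed)
      tab <- data.frame(performance = c("error_rate", "tpr", "fpr", "auc_roc",
                                        "auc_prc", "f1"))
      for (nm in names(cvs)) tab[[nm]] <- summary_row(cvs[[nm]])
      list(table = tab,
           optimal_threshold = list(median = ts$median, deviation = ts$deviation),
           calibration = list(direction = sets$calibration$direction,
                              mse_forward = sets$calibration$mse_forward,
                              mse_backward = sets$calibration$mse_backward))
    },
    threshold_search = {
      say("generate cohorts + calibration")
      sets <- build_fusion(cfg)
      say("grid search")
      ts <- optimize_threshold(sets$fused, predictor_from_config(cfg),
                               rounds = pl$rounds, folds = pl$folds,
                               grid = pl$grid, seed = cfg$seed)
      list(per_round_optima = ts$per_round_optima,
           summary = list(median = ts$median, deviation = ts$deviation),
           criterion = ts$criterion)
    },
    early_prediction = {
      say("generate cohorts")
      sets <- build_fusion(cfg)
      early <- cohort_from_config(cfg, "first_trimester")
      non_early <- sets$fused[!is_early_pregnancy(sets$fused), , drop = FALSE]
      thr <- pl$early_threshold
      say("early-only CV")
      first_tri <- repeated_cv(early, predictor_from_config(cfg, thr),
                               pl$rounds, pl$folds, thr, cfg$seed)
      say("early-enriched CV")
      enriched <- early_enriched_cv(early, non_early, predictor_from_config(cfg, thr),
                                    pl$rounds, pl$folds, thr, cfg$seed)
      tab <- data.frame(performance = c("error_rate", "tpr", "fpr", "auc_roc",
                                        "auc_prc", "f1"),
                        First_Trimester_Results = summary_row(first_tri),
                        Simoa_Elecsys_Results2 = summary_row(enriched))
      list(table = tab, threshold = thr)
    },
    augmentation_study = {
      say("generate elecsys cohort")
      elecsys <- cohort_from_config(cfg, "elecsys")
      say("real-only CV")
      real_cv <- repeated_cv(elecsys, predictor_from_config(cfg),
                             pl$rounds, pl$folds, pl$threshold, cfg$seed)
      say("augmented CV")
      ac <- augmentation_config(cfg$augmentation$method,
                                cfg$augmentation$target_ratio,
                                cfg$augmentation$k_neighbors,
                                seed = derive_seed(cfg$seed, "augment"))
      aug <- augmented_real_test_cv(elecsys, ac, predictor_from_config(cfg),
                                    rounds = pl$rounds, folds = pl$folds,
                                    threshold = pl$threshold, seed = cfg$seed)
      tab <- data.frame(performance = c("error_rate", "tpr", "fpr", "auc_roc",
                                        "auc_prc", "f1"),
                        real_train_real_test = summary_row(real_cv),
                        aug_train_aug_test = summary_row(aug$real_aug),
                        aug_train_real_test = summary_row(aug$real_only))
      list(table = tab)
    })

  report <- c(list(experiment = name, stages = stages, seed = cfg$seed,
                   config = unclass(cfg)), report)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  writeLines(render_report(report), file.path(out_dir, paste0(name, ".txt")))
  say("report written")
  invisible(report)
}

#' Render a report as an aligned text table
#' @param report a [run_experiment()] result (or a path to its JSON file).
#' @return character vector of lines.
#' @export
render_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = TRUE)
  lines <- c(sprintf("experiment: %s (seed %s)", report$experiment, report$seed), "")
  if (!is.null(report$table)) {
    tab <- as.data.frame(report$table)
    widths <- vapply(names(tab), function(nm)
      max(nchar(c(nm, as.character(tab[[nm]])))), 0L)
    pad <- function(v, w) formatC(v, width = w, flag = "-")
    lines <- c(lines,
               paste(mapply(pad, names(tab), widths), collapse = "  "),
               vapply(seq_len(nrow(tab)), function(i)
                 paste(mapply(function(nm, w) pad(as.character(tab[i, nm]), w),
                              names(tab), widths), collapse = "  "), ""))
  }
  if (!is.null(report$summary))
    lines <- c(lines, sprintf("summary: %.4f ± %.4f",
                              report$summary$median, report$summary$deviation))
  if (!is.null(report$optimal_threshold))
    lines <- c(lines, sprintf("optimal threshold: %.2f ± %.4f",
                              report$optimal_threshold$median,
                              report$optimal_threshold$deviation))
  lines
}
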