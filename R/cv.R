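#' Repeated and modified cross-validation protocols
#'
#' Model assessment follows a repeated k-fold design: each round draws a
#' fresh simple-random fold assignment, out-of-fold risk scores are pooled
#' within the round and scored once, and the rounds are summarized as
#' median +/- deviation (median absolute deviation about the median), which
#' is robust to the occasional pathological round that small imbalanced
#' cohorts produce. All preprocessing — imputation model and min-max
#' normalizer — is refit inside every training fold so no information leaks
#' from held-out records.
#'
#' @name cross-validation
NULL

# full per-fold pipeline: encode -> fit/apply imputer -> fit/apply normalizer
# -> train -> score the held-out records
pipeline_scores <- function(train_table, test_table, config) {
  tr <- encode(train_table)
  imp <- fit_imputer(tr, seed = config$seed)
  tr <- impute_train(tr, imp)
  te <- impute_test(encode(test_table), imp)
  tr <- fit_normalizer(tr)
  te <- apply_normalizer(te, tr$normalizer)
  model <- train_model(tr, config)
  predict_risk(model, te)$score
}

# one round of out-of-fold scores over `fold_table`; `extra_train` rows (the
# early-enrichment protocol) join every training fold and are never tested
oof_scores <- function(fold_table, config, folds, seed, extra_train = NULL,
                       stratified = FALSE) {
  n <- nrow(fold_table)
  if (n < folds) stopf("fewer records (%d) than folds (%d)", n, folds)
  set.seed(as.integer(seed))
  for (try in 1:50) {
    if (stratified) {
      fold_of <- integer(n)
      for (cl in unique(fold_table$label)) {
        rows <- which(fold_table$label == cl)
        fold_of[rows] <- sample(rep_len(seq_len(folds), length(rows)))
      }
    } else {
      fold_of <- sample(rep_len(seq_len(folds), n))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      lab <- c(as.character(fold_table$label[fold_of != f]),
               as.character(extra_train$label))
      length(unique(lab)) == 2L
    }, TRUE))
    if (ok) break
    if (try == 50) stopf("could not draw folds with two-class training sets")
  }
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    test_rows <- fold_of == f
    train_tab <- fold_table[!test_rows, , drop = FALSE]
    if (!is.null(extra_train) && nrow(extra_train))
      train_tab <- rbind(train_tab, extra_train)
    scores[test_rows] <- suppressWarnings(
      pipeline_scores(train_tab, fold_table[test_rows, , drop = FALSE], config))
  }
  list(scores = scores, labels = fold_table$label, fold_of = fold_of)
}

summarize_rounds <- function(per_round) {
  keys <- c("error_rate", "tpr", "fpr", "tnr", "fnr", "f1", "auc_roc", "auc_prc")
  pull <- function(k) vapply(per_round, function(m) m[[k]], 0)
  summary <- lapply(keys, function(k) {
    v <- pull(k)
    list(median = median(v), deviation = deviation_about_median(v))
  })
  names(summary) <- keys
  # micro-F1: F1 of the round-averaged confusion matrix; macro-F1: harmonic
  # mean of round-averaged precision and recall. Both collapse to plain F1
  # for a single round.
  tp <- mean(pull("tp")); fp <- mean(pull("fp")); fn <- mean(pull("fn"))
  summary$micro_f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  mp <- mean(pull("precision")); mr <- mean(pull("tpr"))
  summary$macro_f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  summary
}

new_cv_result <- function(per_round, protocol, rounds, folds, threshold, seed) {
  structure(list(per_round = per_round, summary = summarize_rounds(per_round),
                 protocol = protocol, rounds = as.integer(rounds),
                 folds = as.integer(folds), threshold = threshold,
                 seed = as.integer(seed)),
            class = "perisk_cv_result")
}

#' Repeated k-fold cross-validation of the full pipeline
#'
#' @param table a labelled cohort `data.frame`.
#' @param config a [predictor_config()].
#' @param rounds number of repetitions (paper-scale default is 100; pass a
#'   smaller value for desk-scale runs).
#' @param folds folds per round.
#' @param threshold decision cut applied to the pooled out-of-fold scores.
#' @param seed integer seed.
#' @param stratified draw folds within class strata instead of simple random
#'   assignment (off by default, matching the plain protocol).
#' @return an object of class `perisk_cv_result`: `per_round` metric bundles
#'   and a `summary` of per-metric `median`/`deviation` plus `micro_f1` and
#'   `macro_f1` aggregated across rounds.
#' @export
repeated_cv <- function(table, config = predictor_config(), rounds = 10L,
                        folds = 10L, threshold = 0.5, seed = 0L,
                        stratified = FALSE) {
  early_enriched_cv(table, NULL, config, rounds, folds, threshold, seed,
                    stratified = stratified, protocol = "standard")
}

#' Early-pregnancy enriched cross-validation
#'
#' The early-pregnancy set is small, so each round partitions only the early
#' set into folds; every training fold is nine tenths of the early set plus
#' all non-early records, and every test fold is early records only. With an
#' empty non-early set this reduces exactly to [repeated_cv()].
#'
#' @param early labelled cohort table of early-pregnancy records (the fold
#'   set).
#' @param non_early labelled cohort table joined to every training fold
#'   (never tested); `NULL` or zero rows reduce to the standard protocol.
#' @inheritParams repeated_cv
#' @param protocol label stored in the result.
#' @return a `perisk_cv_result`.
#' @export
early_enriched_cv <- function(early, non_early, config = predictor_config(),
                              rounds = 10L, folds = 10L, threshold = 0.5,
                              seed = 0L, stratified = FALSE,
                              protocol = "early_enriched") {
  if (rounds < 1L) stopf("rounds must be >= 1")
  if (folds < 2L) stopf("folds must be >= 2")
  per_round <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    oof <- oof_scores(early, config, folds, derive_seed(seed, paste("cv round", r)),
                      extra_train = non_early, stratified = stratified)
    per_round[[r]] <- suppressWarnings(
      compute_metrics(oof$labels, oof$scores, threshold))
  }
  new_cv_result(per_round, protocol, rounds, folds, threshold, seed)
}

#' Augmentation cross-validation with real-only test partitions
#'
#' Reproduces the evaluation that exposes the "virtually high" performance
#' phenomenon. The real set is preprocessed once (imputed, normalized),
#' minority oversampling is applied to the whole matrix, and each round
#' splits real + augmented rows at random into folds: nine parts train the
#' classifier and the remaining part is scored twice — over all held-out rows
#' (real + augmented) and over the held-out real rows only. Origin flags
#' never enter the feature matrix. Because augmentation precedes splitting,
#' interpolated neighbours leak across folds exactly as in the original
#' protocol; `safe = TRUE` instead folds only the real rows and augments
#' inside each training fold (no leakage, and both result objects coincide
#' because test folds contain no synthetic rows).
#'
#' @param real labelled cohort table of real records.
#' @param augmenter an [augmentation_config()], or a function
#'   `(x, labels, seed)` returning `list(x, labels, origin)`.
#' @inheritParams repeated_cv
#' @param safe leakage-safe variant (augment inside training folds only).
#' @return list with `real_aug` and `real_only`, both `perisk_cv_result`
#'   objects built from the same folds.
#' @export
augmented_real_test_cv <- function(real, augmenter = augmentation_config(),
                                   config = predictor_config(), rounds = 10L,
                                   folds = 10L, threshold = 0.5, seed = 0L,
                                   safe = FALSE) {
  if (rounds < 1L) stopf("rounds must be >= 1")
  run_aug <- if (is.function(augmenter)) augmenter else
    function(x, labels, seed) {
      cfg <- augmenter; cfg$seed <- seed
      augment(x, labels, cfg)
    }
  # paper-style global preprocessing of the real set
  enc <- suppressWarnings({
    tr <- encode(real)
    imp <- fit_imputer(tr, seed = seed)
    fit_normalizer(impute_train(tr, imp))
  })
  x <- enc$x; y <- enc$label

  if (!safe) {
    aug <- run_aug(x, y, derive_seed(seed, "augment"))
    n <- nrow(aug$x)
    real_rows <- aug$origin == "real"
  }
  rounds_all <- vector("list", rounds)
  rounds_real <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    set.seed(derive_seed(seed, paste("aug round", r)))
    if (safe) {
      n <- nrow(x)
      fold_of <- resample_folds(n, folds, function(fold_of)
        all(vapply(seq_len(folds), function(f)
          length(unique(y[fold_of != f])) == 2L, TRUE)))
      sc <- numeric(n)
      for (f in seq_len(folds)) {
        te <- fold_of == f
        a <- run_aug(x[!te, , drop = FALSE], y[!te],
                     derive_seed(seed, paste("aug fold", r, f)))
        model <- train_model(a$x, config, labels = a$labels)
        sc[te] <- predict_risk(model, x[te, , drop = FALSE])$score
      }
      m <- suppressWarnings(compute_metrics(y, sc, threshold))
      rounds_all[[r]] <- m; rounds_real[[r]] <- m
    } else {
      fold_of <- resample_folds(n, folds, function(fold_of)
        all(vapply(seq_len(folds), function(f)
          length(unique(aug$labels[fold_of != f])) == 2L &&
            any(real_rows[fold_of == f]), TRUE)))
      sc <- numeric(n)
      for (f in seq_len(folds)) {
        te <- fold_of == f
        model <- train_model(aug$x[!te, , drop = FALSE], config,
                             labels = aug$labels[!te])
        sc[te] <- predict_risk(model, aug$x[te, , drop = FALSE])$score
      }
      rounds_all[[r]] <- suppressWarnings(
        compute_metrics(aug$labels, sc, threshold))
      rounds_real[[r]] <- suppressWarnings(
        compute_metrics(aug$labels[real_rows], sc[real_rows], threshold))
    }
  }
  list(real_aug = new_cv_result(rounds_all, "augmented_real_test:all",
                                rounds, folds, threshold, seed),
       real_only = new_cv_result(rounds_real, "augmented_real_test:real_only",
                                 rounds, folds, threshold, seed))
}

# draw fold assignments until `valid` accepts them (e.g. every test fold must
# keep at least one real record); assignment uses the current RNG stream
resample_folds <- function(n, folds, valid) {
  for (try in 1:50) {
    fold_of <- sample(rep_len(seq_len(folds), n))
    if (valid(fold_of)) return(fold_of)
  }
  stopf("could not draw an admissible fold assignment in 50 tries")
}

#' Export a cross-validation result
#'
#' Writes the per-round metrics and the summary as JSON, and optionally the
#' per-round metrics as a flat CSV.
#'
#' @param result a `perisk_cv_result`.
#' @param json_path JSON output path.
#' @param csv_path optional CSV output path for per-round metrics.
#' @export
write_cv_result <- function(result, json_path, csv_path = NULL) {
  stopifnot(inherits(result, "perisk_cv_result"))
  rounds_df <- cv_rounds_frame(result)
  out <- list(protocol = result$protocol, rounds = result$rounds,
              folds = result$folds, threshold = result$threshold,
              seed = result$seed, summary = result$summary,
              per_round = rounds_df)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(csv_path)) write.csv(rounds_df, csv_path, row.names = FALSE)
  invisible(json_path)
}

cv_rounds_frame <- function(result) {
  keys <- c("error_rate", "tpr", "fpr", "tnr", "fnr", "precision", "f1",
            "auc_roc", "auc_prc", "tp", "fp", "tn", "fn")
  df <- as.data.frame(lapply(setNames(keys, keys), function(k)
    vapply(result$per_round, function(m) as.numeric(m[[k]]), 0)))
  cbind(round = seq_len(nrow(df)), df)
}
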