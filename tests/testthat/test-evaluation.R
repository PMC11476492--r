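rf_tiny <- function(seed = 1) predictor_config("rf", list(ntree = 25), seed = seed)

test_that("a constant-score predictor gives the degenerate bundle", {
  y <- c(rep(1, 20), rep(0, 80))
  m <- compute_metrics(y, rep(0.3, 100), threshold = 0.5)
  expect_equal(m$tpr, 0)
  expect_equal(m$fpr, 0)
  expect_equal(m$error_rate, 0.2)                  # the case prevalence
})

test_that("single-round summaries collapse to the round itself", {
  co <- tiny_cohort(n_cases = 15, n_controls = 45, seed = 1)
  res <- repeated_cv(co, rf_tiny(), rounds = 1, folds = 4, seed = 2)
  expect_length(res$per_round, 1)
  m <- res$per_round[[1]]
  expect_equal(res$summary$auc_roc$median, m$auc_roc)
  expect_equal(res$summary$auc_roc$deviation, 0)
  expect_equal(res$summary$error_rate$median, m$error_rate)
  # micro/macro F1 collapse to plain F1 for a single round
  expect_equal(res$summary$micro_f1, m$f1)
  if (m$precision + m$tpr > 0)
    expect_equal(res$summary$macro_f1,
                 2 * m$precision * m$tpr / (m$precision + m$tpr))
})

test_that("summary medians equal an independent order-statistic recomputation", {
  co <- tiny_cohort(n_cases = 15, n_controls = 45, seed = 3)
  res <- repeated_cv(co, rf_tiny(), rounds = 3, folds = 4, seed = 4)
  errs <- vapply(res$per_round, function(m) m$error_rate, 0)
  expect_equal(res$summary$error_rate$median, median(errs))
  expect_equal(res$summary$error_rate$deviation, median(abs(errs - median(errs))))
  expect_gte(res$summary$error_rate$deviation, 0)
})

test_that("fold partitions are disjoint, exhaustive and balanced within one", {
  co <- tiny_cohort(n_cases = 20, n_controls = 43, seed = 5)
  cfg <- rf_tiny()
  oof <- perisk:::oof_scores(co, cfg, 5, seed = 11)
  expect_length(oof$fold_of, nrow(co))
  sizes <- table(oof$fold_of)
  expect_length(sizes, 5)
  expect_lte(diff(range(sizes)), 1)
  # stratified option balances classes per fold within one record
  oof_s <- perisk:::oof_scores(co, cfg, 5, seed = 11, stratified = TRUE)
  per_fold_cases <- tapply(co$label == "case", oof_s$fold_of, sum)
  expect_lte(diff(range(per_fold_cases)), 1)
})

test_that("early-enriched CV reduces exactly to standard CV with empty enrichment", {
  co <- tiny_cohort(n_cases = 15, n_controls = 45, seed = 6)
  a <- repeated_cv(co, rf_tiny(), rounds = 2, folds = 4, seed = 7)
  b <- early_enriched_cv(co, NULL, rf_tiny(), rounds = 2, folds = 4, seed = 7,
                         protocol = "standard")
  expect_equal(a$per_round, b$per_round)
})

test_that("early-enriched folds test every early record exactly once per round", {
  early <- tiny_cohort(n_cases = 10, n_controls = 30, seed = 8)
  non_early <- tiny_cohort(n_cases = 20, n_controls = 60, seed = 9)
  cfg <- rf_tiny()
  oof <- perisk:::oof_scores(early, cfg, 4, seed = 12, extra_train = non_early)
  # every early record belongs to exactly one test fold; union = early set
  expect_equal(sort(unique(oof$fold_of)), 1:4)
  expect_length(oof$scores, nrow(early))
  res <- early_enriched_cv(early, non_early, cfg, rounds = 1, folds = 4, seed = 12)
  expect_equal(res$per_round[[1]]$n, nrow(early))  # tested on early only
  expect_error(early_enriched_cv(early[1:3, ], non_early, cfg,
                                 rounds = 1, folds = 4, seed = 1), "folds")
})

test_that("an identity augmenter makes both augmented-CV result objects identical", {
  co <- tiny_cohort(n_cases = 15, n_controls = 45, missing_rate = 0.1, seed = 10)
  identity_aug <- function(x, labels, seed)
    list(x = x, labels = labels, origin = rep("real", nrow(x)))
  res <- augmented_real_test_cv(co, identity_aug, rf_tiny(), rounds = 2,
                                folds = 4, seed = 13)
  expect_equal(res$real_aug$per_round, res$real_only$per_round)
})

test_that("real-only metrics are computed over real records exclusively", {
  co <- tiny_cohort(n_cases = 15, n_controls = 45, missing_rate = 0.1, seed = 11)
  ac <- augmentation_config("smote", target_ratio = 0.8, seed = 1)
  res <- augmented_real_test_cv(co, ac, rf_tiny(), rounds = 2, folds = 4, seed = 14)
  for (m in res$real_only$per_round) expect_equal(m$n, nrow(co))
  for (m in res$real_aug$per_round) expect_gt(m$n, nrow(co))
  # the leakage-safe variant never tests synthetic rows, so both sides agree
  safe <- augmented_real_test_cv(co, ac, rf_tiny(), rounds = 1, folds = 4,
                                 seed = 14, safe = TRUE)
  expect_equal(safe$real_aug$per_round, safe$real_only$per_round)
  expect_equal(safe$real_only$per_round[[1]]$n, nrow(co))
})

test_that("results are reproducible under seed and export to JSON/CSV", {
  co <- tiny_cohort(n_cases = 15, n_controls = 45, seed = 12)
  a <- repeated_cv(co, rf_tiny(), rounds = 2, folds = 4, seed = 15)
  b <- repeated_cv(co, rf_tiny(), rounds = 2, folds = 4, seed = 15)
  expect_equal(a$per_round, b$per_round)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_cv_result(a, jp, cp)
  parsed <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(nrow(parsed$per_round), 2)
  expect_equal(parsed$summary$auc_roc$median, a$summary$auc_roc$median)
  expect_equal(nrow(read.csv(cp)), 2)
})
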