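# fast forest for tests
rf_small <- function(seed = 1, threshold = 0.5)
  predictor_config("rf", list(ntree = 40), seed = seed, threshold = threshold)

test_that("every algorithm fits, scores in [0, 1] and is deterministic under seed", {
  enc <- prep(tiny_cohort(seed = 1))
  for (alg in c("rf", "mlp", "svm", "xgb", "ada")) {
    hp <- switch(alg, rf = list(ntree = 20), xgb = list(nrounds = 20),
                 ada = list(nrounds = 20), mlp = list(maxit = 100), list())
    cfg <- predictor_config(alg, hp, seed = 5)
    m1 <- train_model(enc, cfg)
    m2 <- train_model(enc, cfg)
    s1 <- predict_risk(m1, enc)$score
    expect_true(all(s1 >= 0 & s1 <= 1))
    expect_identical(s1, predict_risk(m2, enc)$score)
  }
})

test_that("the forest separates linearly separable data perfectly in-sample", {
  enc <- fake_encoded(60, label = rep(c("case", "control"), each = 30))
  enc$x[, "plgf"] <- ifelse(enc$label == "case", 50, 300) + rnorm(60, 0, 5)
  m <- train_model(enc, rf_small())
  s <- predict_risk(m, enc)$score
  expect_equal(compute_metrics(enc$label, s)$auc_roc, 1)
})

test_that("label-permuted data score near chance out of sample", {
  enc <- prep(tiny_cohort(n_cases = 40, n_controls = 80, missing_rate = 0, seed = 2))
  set.seed(3)
  tr <- sample(nrow(enc$x), 60)
  aucs <- replicate(20, {
    ylab <- sample(enc$label)
    sub <- enc; sub$x <- enc$x[tr, ]; sub$label <- ylab[tr]
    m <- train_model(sub, predictor_config("rf", list(ntree = 25),
                                           seed = sample.int(1e6, 1)))
    s <- predict_risk(m, enc$x[-tr, ])$score
    suppressWarnings(compute_metrics(ylab[-tr], s)$auc_roc)
  })
  expect_gt(mean(aucs, na.rm = TRUE), 0.4)
  expect_lt(mean(aucs, na.rm = TRUE), 0.6)
})

test_that("threshold semantics: call is positive iff score >= threshold", {
  enc <- prep(tiny_cohort(seed = 4))
  m <- train_model(enc, rf_small())
  for (thr in c(0.21, 0.5, 0.8)) {
    pr <- predict_risk(m, enc, threshold = thr)
    expect_identical(pr$call == "case", pr$score >= thr)
  }
  # lowering the threshold never flips a positive call to negative
  hi <- predict_risk(m, enc, threshold = 0.5)$call
  lo <- predict_risk(m, enc, threshold = 0.21)$call
  expect_true(all(lo[hi == "case"] == "case"))
})

test_that("degenerate training inputs are rejected", {
  enc <- prep(tiny_cohort(seed = 5))
  one_class <- enc; one_class$label <- factor(rep("control", nrow(enc$x)),
                                              levels = c("control", "case"))
  expect_error(train_model(one_class, rf_small()), "single class")
  with_na <- enc; with_na$x[1, 1] <- NA
  expect_error(train_model(with_na, rf_small()), "impute")
  m <- train_model(enc, rf_small())
  expect_error(predict_risk(m, enc$x[, 1:10]), "schema")
  expect_error(predictor_config("rf", threshold = 1), "threshold")
})

test_that("per-round optimal threshold equals an exhaustive grid oracle", {
  co <- tiny_cohort(n_cases = 25, n_controls = 60, seed = 6)
  cfg <- predictor_config("rf", list(ntree = 30), seed = 6)
  res <- optimize_threshold(co, cfg, rounds = 2, folds = 4, grid = 0.01, seed = 17)
  expect_length(res$per_round_optima, 2)
  # independent recomputation of round 1 from the same out-of-fold scores
  oof <- perisk:::oof_scores(co, cfg, 4, perisk:::derive_seed(17, "thr round 1"))
  y <- as.integer(oof$labels == "case")
  grid <- seq(0.01, 0.99, by = 0.01)
  f1_manual <- vapply(grid, function(t) {
    tp <- sum(oof$scores >= t & y == 1)
    fp <- sum(oof$scores >= t & y == 0)
    fn <- sum(oof$scores < t & y == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  expect_equal(res$per_round_optima[1], grid[which.max(f1_manual)])
  # optima live on the grid; the summary median lies within their range
  expect_true(all(res$per_round_optima %in% grid))
  expect_gte(res$median, min(res$per_round_optima))
  expect_lte(res$median, max(res$per_round_optima))
  # optimal-threshold F1 is at least the F1 at 0.5 on the same scores
  expect_gte(max(f1_manual), f1_manual[grid == 0.5])

  # TPR and FPR are non-increasing in the threshold over the full grid
  tprs <- vapply(grid, function(t) compute_metrics(y, oof$scores, t)$tpr, 0)
  fprs <- vapply(grid, function(t) compute_metrics(y, oof$scores, t)$fpr, 0)
  expect_true(all(diff(tprs) <= 1e-12))
  expect_true(all(diff(fprs) <= 1e-12))

  # reproducible under the same seed
  res2 <- optimize_threshold(co, cfg, rounds = 2, folds = 4, grid = 0.01, seed = 17)
  expect_identical(res$per_round_optima, res2$per_round_optima)
})

test_that("forest importance is normalized, sorted, and finds the informative feature", {
  enc <- fake_encoded(80, label = rep(c("case", "control"), each = 40))
  set.seed(8)
  enc$x[, "plgf"] <- ifelse(enc$label == "case", 60, 280) + rnorm(80, 0, 20)
  m <- train_model(enc, rf_small(seed = 8))
  imp <- feature_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_true(all(diff(unname(imp)) <= 1e-12))    # sorted descending
  expect_identical(names(imp)[1], "plgf")
})

test_that("pure-noise features produce no stable importance winner", {
  set.seed(9)
  means <- matrix(0, 10, 5)
  for (k in 1:10) {
    x <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(150, 1, 0.5)
    m <- train_model(x, predictor_config("rf", list(ntree = 30), seed = k),
                     labels = y)
    means[k, ] <- unname(feature_importance(m)[paste0("f", 1:5)])
  }
  avg <- colMeans(means)
  expect_lt(max(avg), 3 * min(avg))
})

test_that("importance is refused for non-forest models", {
  enc <- prep(tiny_cohort(seed = 10))
  m <- train_model(enc, predictor_config("svm", seed = 1))
  expect_error(feature_importance(m), "forest")
})
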