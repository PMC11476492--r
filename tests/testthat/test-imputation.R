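# independent median oracle: sort-based, no stats::median
oracle_median <- function(v) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

NO_RELATIONS <- 10^6  # min_pairs high enough that every pair cell falls back to medians

test_that("intra-class and overall medians match the brute-force oracle", {
  enc <- fake_encoded(5, label = c("control", "control", "control", "case", "case"),
                      values = list(age = c(1, 2, 3, 10, 20)))
  model <- fit_imputer(enc, min_pairs = NO_RELATIONS)
  expect_equal(unname(model$intra["age", "control"]), 2)
  expect_equal(unname(model$intra["age", "case"]), 15)
  expect_equal(unname(model$overall[["age"]]), 3)
})

test_that("training imputation uses the record's own class median", {
  enc <- fake_encoded(7, label = c(rep("case", 4), rep("control", 3)),
                      values = list(age = c(25, 30, 41, NA, 1, 2, 3)))
  model <- fit_imputer(enc, min_pairs = NO_RELATIONS)
  out <- impute_train(enc, model)
  expect_equal(unname(out$x[4, "age"]), 30)        # median of case ages
  expect_false(anyNA(out$x))
})

test_that("test imputation uses the overall training median and ignores labels", {
  train <- fake_encoded(5, label = c("control", "control", "control", "case", "case"),
                        values = list(age = c(1, 2, 3, 10, 20)))
  model <- fit_imputer(train, min_pairs = NO_RELATIONS)
  test <- fake_encoded(2, values = list(age = c(NA, 7)))
  out <- impute_test(test, model)
  expect_equal(unname(out$x[1, "age"]), 3)
  expect_equal(unname(out$x[2, "age"]), 7)         # complete values untouched
  # identical tables with and without labels impute identically
  test_lab <- test; test_lab$label <- factor(c("case", "case"),
                                             levels = c("control", "case"))
  expect_identical(impute_test(test_lab, model)$x, out$x)
})

test_that("permuting training labels does not change test-time imputation", {
  co <- tiny_cohort(seed = 21)
  enc <- suppressWarnings(encode(co))
  perm <- enc
  set.seed(1)
  perm$label <- sample(perm$label)
  m1 <- suppressWarnings(fit_imputer(enc, seed = 5))
  m2 <- suppressWarnings(fit_imputer(perm, seed = 5))
  test <- suppressWarnings(encode(tiny_cohort(seed = 22)))
  test$label <- NULL
  expect_equal(impute_test(test, m1)$x, impute_test(test, m2)$x, tolerance = 1e-12)
})

test_that("relation networks recover a noiseless dependent-pair relation", {
  co <- tiny_cohort(n_cases = 50, n_controls = 150, missing_rate = 0,
                    pair_noise_sd = 0, seed = 7)
  enc <- encode(co)
  enc$x[, "systolic_pressure"] <- enc$x[, "diastolic_pressure"] + 40
  enc$x <- perisk:::derive_features(enc$x)
  model <- fit_imputer(enc, seed = 11, maxit = 3000, n_starts = 5)
  set.seed(2)
  mask <- sample(nrow(enc$x), 50)
  truth <- enc$x[mask, "systolic_pressure"]
  masked <- enc
  masked$x[mask, "systolic_pressure"] <- NA
  out <- impute_train(masked, model)
  expect_lt(max(abs(out$x[mask, "systolic_pressure"] - truth)), 1e-2)
  # MAP recomputed from the imputed parents
  expect_equal(out$x[, "map"],
               (out$x[, "systolic_pressure"] + 2 * out$x[, "diastolic_pressure"]) / 3,
               tolerance = 1e-12)
})

test_that("weight-pair relation is recovered within a fixed gestational stratum", {
  enc <- fake_encoded(60, label = rep(c("case", "control"), 30))
  set.seed(3)
  pre <- runif(60, 45, 90)
  enc$x[, "pre_pregnancy_weight"] <- pre
  enc$x[, "current_weight"] <- pre + 4.5          # exact relation, one stratum
  enc$x <- perisk:::derive_features(enc$x)
  model <- fit_imputer(enc, seed = 13, maxit = 3000, n_starts = 5)
  masked <- enc
  masked$x[1:10, "current_weight"] <- NA
  out <- impute_train(masked, model)
  expect_lt(max(abs(out$x[1:10, "current_weight"] - (pre[1:10] + 4.5))), 0.05)
})

test_that("a pair with both members missing falls back to intra-class medians", {
  enc <- fake_encoded(12, label = rep(c("case", "control"), each = 6))
  masked <- enc
  masked$x[1, c("pre_pregnancy_weight", "current_weight")] <- NA
  model <- fit_imputer(masked, min_pairs = NO_RELATIONS)
  out <- impute_train(masked, model)
  case_rows <- 2:6                                 # observed case rows
  expect_equal(unname(out$x[1, "pre_pregnancy_weight"]),
               oracle_median(enc$x[case_rows, "pre_pregnancy_weight"]))
  expect_equal(unname(out$x[1, "current_weight"]),
               oracle_median(enc$x[case_rows, "current_weight"]))
})

test_that("imputation matches an exhaustive median oracle on small tables", {
  co <- tiny_cohort(n_cases = 15, n_controls = 35, missing_rate = 0.3, seed = 31)
  enc <- suppressWarnings(encode(co))
  model <- suppressWarnings(fit_imputer(enc, min_pairs = NO_RELATIONS))
  out <- impute_train(enc, model)
  y <- as.character(enc$label)
  for (j in perisk:::base_features()) {
    for (i in which(is.na(enc$x[, j]))) {
      same_class <- enc$x[y == y[i], j]
      expected <- oracle_median(same_class)
      if (is.na(expected)) expected <- oracle_median(enc$x[, j])
      expect_equal(unname(out$x[i, j]), unname(expected))
    }
  }
  # test-side: overall medians
  test <- enc; test$label <- NULL
  out_t <- impute_test(test, model)
  for (j in perisk:::base_features()) {
    for (i in which(is.na(enc$x[, j]))) {
      expect_equal(unname(out_t$x[i, j]), oracle_median(enc$x[, j]))
    }
  }
})

test_that("imputation is idempotent and the identity on complete data", {
  co <- tiny_cohort(seed = 41)
  enc <- suppressWarnings(encode(co))
  model <- suppressWarnings(fit_imputer(enc, seed = 2))
  once <- impute_train(enc, model)
  twice <- impute_train(once, model)
  expect_identical(once$x, twice$x)

  complete <- encode(tiny_cohort(missing_rate = 0, seed = 42))
  m2 <- fit_imputer(complete, seed = 2)
  expect_equal(impute_train(complete, m2)$x, complete$x, tolerance = 1e-12)
})

test_that("median-imputed values lie within the observed training range", {
  co <- tiny_cohort(seed = 51)
  enc <- suppressWarnings(encode(co))
  model <- suppressWarnings(fit_imputer(enc, min_pairs = NO_RELATIONS))
  out <- impute_train(enc, model)
  for (j in perisk:::base_features()) {
    obs <- enc$x[!is.na(enc$x[, j]), j]
    filled <- out$x[is.na(enc$x[, j]), j]
    if (length(filled))
      expect_true(all(filled >= min(obs) & filled <= max(obs)))
  }
})

test_that("a feature absent from a whole class falls back with a warning", {
  enc <- fake_encoded(8, label = rep(c("case", "control"), each = 4))
  enc$x[1:4, "age"] <- NA                          # all cases missing age
  expect_warning(model <- fit_imputer(enc, min_pairs = NO_RELATIONS), "age")
  out <- impute_train(enc, model)
  expect_equal(unname(out$x[1, "age"]), oracle_median(enc$x[5:8, "age"]))
})

test_that("the imputation model serializes to JSON", {
  enc <- fake_encoded(30, label = rep(c("case", "control"), 15))
  model <- fit_imputer(enc, seed = 3, maxit = 100)
  path <- tempfile(fileext = ".json")
  write_imputer(model, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$strata), 5)           # five gestational strata
  expect_named(parsed$pairs, c("weight", "pressure"))
})
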