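test_that("cohort shape and class counts match the spec exactly", {
  co <- generate_cohort(cohort_spec(n_cases = 145, n_controls = 559, seed = 1))
  expect_equal(nrow(co), 704)
  expect_equal(sum(co$label == "case"), 145)
  expect_equal(sum(co$label == "control"), 559)
  # smaller shapes too
  co2 <- tiny_cohort(n_cases = 7, n_controls = 13, seed = 3)
  expect_equal(as.vector(table(co2$label)), c(13, 7))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_cases = 0), "n_cases")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(pair_noise_sd = -1), "pair_noise_sd")
  expect_error(cohort_spec(gestational_day_range = c(200, 100)), "interval")
})

test_that("missingness injection hits the requested rate and never touches protected columns", {
  co <- generate_cohort(cohort_spec(n_cases = 145, n_controls = 559,
                                    missing_rate = 0.25, seed = 2))
  expect_gt(missing_fraction(co), 0.23)
  expect_lt(missing_fraction(co), 0.27)
  expect_false(anyNA(co$label))
  expect_false(anyNA(co$platform))
  expect_false(anyNA(co$gest_weeks))
  expect_false(anyNA(co$gest_days))

  co0 <- tiny_cohort(missing_rate = 0, seed = 2)
  expect_false(anyNA(co0))
  expect_identical(inject_missingness(co0, 0, seed = 9), co0)
  expect_error(inject_missingness(co0, 1.2, seed = 1), "rate")
})

test_that("identical seeds reproduce byte-identical cohorts, different seeds differ", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  c <- tiny_cohort(seed = 12)
  expect_identical(a, b)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  # byte-identical on disk as well
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("noiseless dependent-pair relations are exactly recoverable by regression", {
  co <- tiny_cohort(n_cases = 100, n_controls = 200, missing_rate = 0,
                    pair_noise_sd = 0, seed = 4)
  fit_bp <- lm(systolic_pressure ~ diastolic_pressure, data = co)
  expect_equal(unname(coef(fit_bp)), c(perisk:::SBP_INTERCEPT, perisk:::SBP_SLOPE),
               tolerance = 1e-6)
  gd <- 7 * co$gest_weeks + co$gest_days
  fit_w <- lm(current_weight ~ pre_pregnancy_weight + gd, data = co)
  # current weight is rounded to 0.1 kg in the table, hence the tolerance
  expect_equal(unname(coef(fit_w)), c(0, 1, perisk:::WEIGHT_GAIN_PER_DAY),
               tolerance = 0.02)
})

test_that("class-conditional shifts have the configured sign", {
  for (seed in 1:3) {
    co <- tiny_cohort(n_cases = 100, n_controls = 150, missing_rate = 0, seed = seed)
    expect_lt(mean(co$plgf[co$label == "case"]),
              mean(co$plgf[co$label == "control"]))
    expect_gt(mean(co$diastolic_pressure[co$label == "case"]),
              mean(co$diastolic_pressure[co$label == "control"]))
  }
})

test_that("record-level invariants hold on generated cohorts", {
  co <- tiny_cohort(seed = 6)
  both <- !is.na(co$systolic_pressure) & !is.na(co$diastolic_pressure)
  expect_true(all(co$systolic_pressure[both] >= co$diastolic_pressure[both]))
  expect_true(all(co$height[!is.na(co$height)] > 0))
  expect_true(all(co$plgf[!is.na(co$plgf)] > 0))
})

test_that("calibration pair sets have the stated size, positivity and transfer", {
  ps <- generate_calibration_set(24, seed = 1)
  expect_equal(nrow(ps), 24)
  expect_false(anyNA(ps))
  expect_true(all(ps$simoa > 0 & ps$elecsys > 0))

  ident <- generate_calibration_set(24, list(slope = 1, intercept = 0, noise_sd = 0),
                                    seed = 2)
  expect_equal(ident$elecsys, ident$simoa)

  aff <- generate_calibration_set(50, list(slope = 2, intercept = 5, noise_sd = 0),
                                  seed = 3)
  expect_equal(unname(coef(lm(elecsys ~ simoa, data = aff))), c(5, 2),
               tolerance = 1e-6)
  expect_error(generate_calibration_set(2, seed = 1), "3")
})

test_that("cohort and calibration tables round-trip through CSV with a spec sidecar", {
  co <- tiny_cohort(seed = 8)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(as.data.frame(co), as.data.frame(back),
               ignore_attr = TRUE, tolerance = 1e-12)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$seed, attr(co, "spec")$seed)

  ps <- generate_calibration_set(10, seed = 5)
  p2 <- tempfile(fileext = ".csv")
  write_calibration_set(ps, p2)
  expect_equal(as.data.frame(read_calibration_set(p2)), as.data.frame(ps),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("early-pregnancy window is 11w+0d through 13w+6d", {
  co <- data.frame(gest_weeks = c(10, 11, 13, 13, 14, 30),
                   gest_days = c(6, 0, 6, 0, 0, 0))
  expect_equal(is_early_pregnancy(co), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})
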