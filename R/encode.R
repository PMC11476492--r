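#' The 22-column design matrix
#'
#' Fourteen collected variables expand to 22 numeric features: age; five
#' one-hot ethnicity indicators; height; pre-pregnancy and current weight;
#' pre-pregnancy BMI, current BMI and BMI increase rate (derived); five
#' history codes; gestational day (7 * weeks + days, used instead of
#' gestational week); diastolic and systolic pressure; mean arterial pressure
#' MAP = (SBP + 2 DBP) / 3 (derived); and PlGF.
#'
#' @name encoded-matrix
#' @keywords internal
NULL

FEATURES_22 <- c("age", paste0("eth_", ETHNICITY_LEVELS), "height",
                 "pre_pregnancy_weight", "current_weight",
                 "pre_pregnancy_bmi", "current_bmi", "bmi_increase_rate",
                 "pregnancy_history", "fertility_history", "pe_history",
                 "family_pe_history", "hypertension_history",
                 "gestational_day", "diastolic_pressure", "systolic_pressure",
                 "map", "plgf")

# features whose values are computed from parents; recomputed after the
# parents are imputed
DERIVED_FEATURES <- c("pre_pregnancy_bmi", "current_bmi", "bmi_increase_rate", "map")

# the two strongly dependent feature pairs (a, b); the weight pair is
# additionally stratified over gestational intervals when imputed
DEPENDENT_PAIRS <- list(
  weight = c("pre_pregnancy_weight", "current_weight"),
  pressure = c("diastolic_pressure", "systolic_pressure"))

#' Encode clinical records into the 22-feature design matrix
#'
#' Derivations: BMI = weight / height^2, BMI increase rate =
#' (current BMI - pre-pregnancy BMI) / pre-pregnancy BMI,
#' MAP = (systolic + 2 diastolic) / 3, gestational day = 7 weeks + days.
#' Ethnicity is one-hot over Han/Uygur/Kazak/Hui/other; unknown levels map to
#' "other" with a warning. Missing inputs propagate to missing derived
#' outputs. Row order is preserved.
#'
#' @param table a cohort `data.frame` (see [generate_cohort()] for the
#'   schema); the `label` column may be absent for test-role tables.
#' @return an object of class `perisk_encoded`: list with `x` (numeric matrix,
#'   22 named columns), `label` (factor or `NULL`), `platform` (factor or
#'   `NULL`), and `normalizer` (`NULL` until fitted).
#' @export
#' @examples
#' enc <- encode(generate_cohort(cohort_spec(n_cases = 5, n_controls = 5,
#'                                           missing_rate = 0)))
#' dim(enc$x)
encode <- function(table) {
  n <- nrow(table)
  if (!is.null(table$height) && any(!is.na(table$height) & table$height <= 0))
    stopf("non-positive height in record(s) %s",
          paste(which(!is.na(table$height) & table$height <= 0), collapse = ", "))

  eth <- as.character(table$ethnicity)
  unknown <- !is.na(eth) & !(eth %in% ETHNICITY_LEVELS)
  if (any(unknown)) {
    warnf("%d record(s) with unknown ethnicity mapped to 'other'", sum(unknown))
    eth[unknown] <- "other"
  }
  onehot <- matrix(NA_real_, n, length(ETHNICITY_LEVELS),
                   dimnames = list(NULL, paste0("eth_", ETHNICITY_LEVELS)))
  known <- !is.na(eth)
  for (lv in ETHNICITY_LEVELS) onehot[known, paste0("eth_", lv)] <-
    as.numeric(eth[known] == lv)

  x <- cbind(age = as.numeric(table$age), onehot,
             height = as.numeric(table$height),
             pre_pregnancy_weight = as.numeric(table$pre_pregnancy_weight),
             current_weight = as.numeric(table$current_weight),
             pre_pregnancy_bmi = NA_real_, current_bmi = NA_real_,
             bmi_increase_rate = NA_real_,
             pregnancy_history = as.numeric(table$pregnancy_history),
             fertility_history = as.numeric(table$fertility_history),
             pe_history = as.numeric(table$pe_history),
             family_pe_history = as.numeric(table$family_pe_history),
             hypertension_history = as.numeric(table$hypertension_history),
             gestational_day = as.numeric(gestational_day(table)),
             diastolic_pressure = as.numeric(table$diastolic_pressure),
             systolic_pressure = as.numeric(table$systolic_pressure),
             map = NA_real_, plgf = as.numeric(table$plgf))
  x <- derive_features(x)
  stopifnot(identical(colnames(x), FEATURES_22))
  structure(list(x = x,
                 label = if (!is.null(table$label)) factor(table$label,
                                                           levels = c("control", "case")),
                 platform = table$platform, normalizer = NULL),
            class = "perisk_encoded")
}

# recompute derived columns from their (possibly imputed) parents
derive_features <- function(x) {
  x[, "pre_pregnancy_bmi"] <- x[, "pre_pregnancy_weight"] / x[, "height"]^2
  x[, "current_bmi"] <- x[, "current_weight"] / x[, "height"]^2
  x[, "bmi_increase_rate"] <-
    (x[, "current_bmi"] - x[, "pre_pregnancy_bmi"]) / x[, "pre_pregnancy_bmi"]
  x[, "map"] <- (x[, "systolic_pressure"] + 2 * x[, "diastolic_pressure"]) / 3
  x
}

#' Fit min-max normalization on a training matrix
#'
#' Rescales every feature except PlGF to `[0, 1]` via `(x - min) / (max -
#' min)` with the extremes taken over non-missing training values, and stores
#' them so test data can be transformed identically. Constant columns are
#' left unscaled with a warning.
#'
#' @param enc a `perisk_encoded` object playing the training role.
#' @return `enc` rescaled, with `$normalizer` attached.
#' @export
fit_normalizer <- function(enc) {
  stopifnot(inherits(enc, "perisk_encoded"))
  lo <- apply(enc$x, 2, min, na.rm = TRUE)
  hi <- apply(enc$x, 2, max, na.rm = TRUE)
  scale <- setNames(rep(TRUE, ncol(enc$x)), colnames(enc$x))
  scale["plgf"] <- FALSE
  const <- hi - lo < 1e-12 & scale
  if (any(const)) {
    warnf("constant column(s) left unscaled: %s",
          paste(names(which(const)), collapse = ", "))
    scale[const] <- FALSE
  }
  normalizer <- list(min = lo, max = hi, scale = scale)
  enc <- apply_normalizer(enc, normalizer)
  enc$normalizer <- normalizer
  enc
}

#' Apply a fitted normalizer to new data
#'
#' Test values outside the training range are clipped to `[0, 1]`.
#'
#' @param enc a `perisk_encoded` object.
#' @param normalizer the `$normalizer` of a [fit_normalizer()] result.
#' @return `enc` with rescaled `x` and the normalizer attached.
#' @export
apply_normalizer <- function(enc, normalizer) {
  stopifnot(inherits(enc, "perisk_encoded"))
  x <- enc$x
  for (j in colnames(x)) {
    if (!normalizer$scale[[j]]) next
    x[, j] <- pmin(pmax((x[, j] - normalizer$min[[j]]) /
                          (normalizer$max[[j]] - normalizer$min[[j]]), 0), 1)
  }
  enc$x <- x
  enc$normalizer <- normalizer
  enc
}

#' Undo min-max normalization (training data round-trip)
#' @inheritParams apply_normalizer
#' @return `enc` on the original scale, normalizer dropped.
#' @export
denormalize <- function(enc, normalizer = enc$normalizer) {
  stopifnot(inherits(enc, "perisk_encoded"), !is.null(normalizer))
  x <- enc$x
  for (j in colnames(x)) {
    if (!normalizer$scale[[j]]) next
    x[, j] <- x[, j] * (normalizer$max[[j]] - normalizer$min[[j]]) + normalizer$min[[j]]
  }
  enc$x <- x
  enc$normalizer <- NULL
  enc
}

#' Serialize a fitted normalizer to JSON
#' @param normalizer a fitted normalizer.
#' @param path JSON path.
#' @export
write_normalizer <- function(normalizer, path) {
  jsonlite::write_json(lapply(normalizer, as.list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  raw <- jsonlite::read_json(path)
  list(min = unlist(raw$min), max = unlist(raw$max),
       scale = unlist(raw$scale))
}
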