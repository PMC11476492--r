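#' Dual-strategy missing-data imputation
#'
#' Training data carry class labels, so independent features are imputed with
#' the intra-class median (the median of the feature over non-missing training
#' values of the record's own class); test data carry no labels and use the
#' overall training median. The two strongly dependent pairs — pre-pregnancy
#' vs. current weight and diastolic vs. systolic pressure — are imputed
#' through their mutual relation instead: small sigmoidal regression networks
#' are fitted in both directions on rows where both members are present, and
#' a missing member is predicted from the present one. Only when both members
#' are missing does the pair fall back to medians. Because current weight
#' varies with gestational age, the weight pair's relation networks are
#' fitted per gestational stratum (11--13+6, 14--18+6, 19--23+6, 24--28+6 and
#' 29--33+6 weeks); the pressure pair is not gestationally stratified.
#'
#' Training-time relation networks are class-specific; test records have no
#' class, so test-time imputation uses pooled (label-free) refits. Imputation
#' operates on encoded but pre-normalization values, and derived features
#' (BMIs, BMI increase rate, MAP) are recomputed from their imputed parents.
#'
#' @name imputation
NULL

# gestational strata for the weight pair, in days (weeks 11-13+6 .. 29-33+6)
WEIGHT_STRATA <- rbind(c(77L, 97L), c(98L, 132L), c(133L, 167L),
                       c(168L, 202L), c(203L, 237L))

weight_stratum <- function(gestational_day) {
  s <- findInterval(gestational_day, WEIGHT_STRATA[, 1])
  pmin(pmax(s, 1L), nrow(WEIGHT_STRATA))
}

# feature columns imputed directly (everything that is not derived; derived
# columns are recomputed from parents afterwards)
base_features <- function() setdiff(FEATURES_22, DERIVED_FEATURES)

#' Fit the imputation model on labelled training data
#'
#' @param train a `perisk_encoded` object with non-`NULL` `$label`
#'   (pre-normalization values).
#' @param min_pairs minimum number of complete pairs needed to fit a relation
#'   network in a class/stratum cell; below it the cell falls back to medians.
#' @param hidden hidden units of each relation network.
#' @param seed integer seed for the network initialisations.
#' @param maxit,n_starts optimisation effort per relation network; the
#'   defaults favour speed inside cross-validation folds, raise them when a
#'   single high-precision imputer is wanted.
#' @return an object of class `perisk_imputer`.
#' @export
fit_imputer <- function(train, min_pairs = 10L, hidden = 2L, seed = 0L,
                        maxit = 500L, n_starts = 1L) {
  stopifnot(inherits(train, "perisk_encoded"))
  if (is.null(train$label)) stopf("fit_imputer needs a labelled training matrix")
  x <- train$x
  y <- as.character(train$label)
  classes <- c("control", "case")
  feats <- base_features()

  overall <- vapply(feats, function(j) median(x[, j], na.rm = TRUE), 0)
  intra <- sapply(classes, function(cl)
    vapply(feats, function(j) {
      v <- x[y == cl, j]
      if (all(is.na(v))) {
        warnf("feature '%s' missing in every %s row; intra-class median falls back to overall", j, cl)
        return(overall[[j]])
      }
      median(v, na.rm = TRUE)
    }, 0))

  fit_cell <- function(rows, a, b, tag) {
    both <- rows[!is.na(x[rows, a]) & !is.na(x[rows, b])]
    if (length(both) < min_pairs) return(list(to_a = NULL, to_b = NULL, n = length(both)))
    set.seed(derive_seed(seed, paste("imputer", tag)))
    list(to_a = mlp_fit(x[both, b], x[both, a], hidden = hidden,
                        maxit = maxit, n_starts = n_starts),
         to_b = mlp_fit(x[both, a], x[both, b], hidden = hidden,
                        maxit = maxit, n_starts = n_starts),
         n = length(both))
  }

  strat <- weight_stratum(x[, "gestational_day"])
  pairs <- list()
  for (pname in names(DEPENDENT_PAIRS)) {
    ab <- DEPENDENT_PAIRS[[pname]]
    cells <- list()
    groups <- c(classes, "pooled")
    for (g in groups) {
      rows <- if (g == "pooled") seq_len(nrow(x)) else which(y == g)
      if (pname == "weight") {
        cells[[g]] <- lapply(seq_len(nrow(WEIGHT_STRATA)), function(s)
          fit_cell(rows[strat[rows] == s], ab[1], ab[2],
                   paste(pname, g, s)))
      } else {
        cells[[g]] <- fit_cell(rows, ab[1], ab[2], paste(pname, g))
      }
    }
    pairs[[pname]] <- cells
  }

  structure(list(intra = intra, overall = overall, features = feats,
                 pairs = pairs, min_pairs = as.integer(min_pairs),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "perisk_imputer")
}

# impute one dependent pair over all rows; `cell_for_row` maps a row index to
# its relation-network cell; `med` maps (row, feature) to the fallback median
impute_pair <- function(x, a, b, cell_for_row, med) {
  miss_a <- is.na(x[, a]); miss_b <- is.na(x[, b])
  # partner present: relation network (fall back to median when no network)
  for (i in which(miss_a & !miss_b)) {
    cell <- cell_for_row(i)
    x[i, a] <- if (!is.null(cell$to_a)) predict(cell$to_a, x[i, b]) else med(i, a)
  }
  for (i in which(miss_b & !miss_a)) {
    cell <- cell_for_row(i)
    x[i, b] <- if (!is.null(cell$to_b)) predict(cell$to_b, x[i, a]) else med(i, b)
  }
  # both missing: medians for both members
  for (i in which(miss_a & miss_b)) {
    x[i, a] <- med(i, a)
    x[i, b] <- med(i, b)
  }
  x
}

impute_core <- function(enc, model, medians_for_row, group_for_row) {
  x <- enc$x
  if (!all(model$features %in% colnames(x)))
    stopf("encoded matrix lacks features known to the imputation model")
  strat <- weight_stratum(x[, "gestational_day"])
  pair_members <- unlist(DEPENDENT_PAIRS)

  med <- function(i, j) medians_for_row(i)[[j]]
  for (pname in names(DEPENDENT_PAIRS)) {
    ab <- DEPENDENT_PAIRS[[pname]]
    cells <- model$pairs[[pname]]
    cell_for_row <- if (pname == "weight") {
      function(i) cells[[group_for_row(i)]][[strat[i]]]
    } else {
      function(i) cells[[group_for_row(i)]]
    }
    x <- impute_pair(x, ab[1], ab[2], cell_for_row, med)
  }
  for (j in setdiff(model$features, pair_members)) {
    miss <- which(is.na(x[, j]))
    for (i in miss) x[i, j] <- med(i, j)
  }
  x <- derive_features(x)
  if (anyNA(x[, c(setdiff(FEATURES_22, DERIVED_FEATURES), DERIVED_FEATURES)]))
    stopf("imputation left missing values behind")
  enc$x <- x
  enc
}

#' Impute a labelled training matrix
#'
#' Uses the record's own class: intra-class medians for independent features
#' and the class-specific relation network (per gestational stratum for the
#' weight pair) when one member of a dependent pair is present. Both members
#' missing fall back to their intra-class medians.
#'
#' @param train a labelled `perisk_encoded` object.
#' @param model a fitted [fit_imputer()] model.
#' @return the encoded object with zero missing entries.
#' @export
impute_train <- function(train, model) {
  stopifnot(inherits(model, "perisk_imputer"))
  if (is.null(train$label)) stopf("impute_train needs labels")
  y <- as.character(train$label)
  impute_core(train, model,
              medians_for_row = function(i) model$intra[, y[i]],
              group_for_row = function(i) y[i])
}

#' Impute an unlabelled test matrix
#'
#' Never consults labels: independent features take the overall training
#' median; dependent-pair members are predicted by the pooled (label-free)
#' relation networks when the partner is present, else the overall medians.
#'
#' @param test a `perisk_encoded` object (any `$label` is ignored).
#' @param model a fitted [fit_imputer()] model.
#' @return the encoded object with zero missing entries.
#' @export
impute_test <- function(test, model) {
  stopifnot(inherits(model, "perisk_imputer"))
  impute_core(test, model,
              medians_for_row = function(i) model$overall,
              group_for_row = function(i) "pooled")
}

#' Serialize an imputation model to JSON
#' @param model a `perisk_imputer`.
#' @param path JSON path.
#' @export
write_imputer <- function(model, path) {
  ser_mlp <- function(m) if (is.null(m)) NULL else unclass(m)
  ser_cell <- function(cell) list(to_a = ser_mlp(cell$to_a),
                                  to_b = ser_mlp(cell$to_b), n = cell$n)
  pairs <- lapply(model$pairs, function(cells) lapply(cells, function(g)
    if (is.null(g$n)) lapply(g, ser_cell) else ser_cell(g)))
  out <- list(intra = apply(model$intra, 2, as.list), overall = as.list(model$overall),
              features = model$features, strata = as.data.frame(WEIGHT_STRATA),
              pairs = pairs, min_pairs = model$min_pairs,
              hidden = model$hidden, seed = model$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
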