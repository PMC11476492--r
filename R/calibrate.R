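#' Cross-platform PlGF calibration by median-model selection
#'
#' PlGF measured on the Elecsys platform is not directly comparable with
#' SiMoA measurements. With only a small paired calibration set available,
#' single train/validation splits give unstable regressors, so calibration
#' proceeds by repeated cross-validation over a pool of small networks:
#' for each direction (SiMoA -> Elecsys and Elecsys -> SiMoA) a
#' 1-input / 2-sigmoidal-hidden / 1-linear-output network is trained on each
#' fold complement of each round, giving `rounds * folds` candidate models per
#' direction, each scored by its held-out mean squared error. The deployed
#' model is the one whose MSE is the pool median — neither a lucky nor an
#' unlucky split — and the direction with the smaller selected-model MSE
#' determines the reference platform: the output side needs no calibration,
#' the other side is mapped through the selected network.
#'
#' @param pairs a `perisk_calpairs` data frame (columns `simoa`, `elecsys`).
#' @param rounds number of cross-validation rounds (default 100).
#' @param folds folds per round (default 3).
#' @param seed integer master seed.
#' @param hidden hidden units per network.
#' @param maxit BFGS iteration cap per network.
#' @param n_starts random restarts per network (best training loss kept).
#' @return an object of class `perisk_calibration` with elements `direction`
#'   (`"simoa_to_elecsys"` or `"elecsys_to_simoa"`), `selected` (the deployed
#'   network), `mse_forward`/`mse_backward` (selected-model MSEs of the two
#'   directions, raw pg/mL scale), `pools` (per-direction MSE vectors and
#'   models) and `reference_platform`.
#' @export
#' @examples
#' pairs <- generate_calibration_set(24, list(slope = 2, intercept = 5,
#'                                            noise_sd = 0), seed = 1)
#' cal <- fit_calibrators(pairs, rounds = 5, folds = 3, seed = 1)
#' calibrate(c(25, 45), "Elecsys", cal)
fit_calibrators <- function(pairs, rounds = 100L, folds = 3L, seed = 0L,
                            hidden = 2L, maxit = 1000L, n_starts = 3L) {
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  if (n < folds) stopf("need at least %d pairs for %d-fold CV, got %d", folds, folds, n)
  if (rounds < 1L) stopf("rounds must be >= 1")
  if (!all(is.finite(pairs$simoa)) || !all(is.finite(pairs$elecsys)))
    stopf("non-finite PlGF value in calibration pairs")

  directions <- list(forward = c(inp = "simoa", out = "elecsys"),
                     backward = c(inp = "elecsys", out = "simoa"))
  pools <- lapply(directions, function(d) list(models = vector("list", rounds * folds),
                                               mse = numeric(rounds * folds)))
  k <- 0L
  for (r in seq_len(rounds)) {
    set.seed(derive_seed(seed, paste("calfold", r)))
    fold_of <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      k <- k + 1L
      tr <- fold_of != f
      for (dn in names(directions)) {
        d <- directions[[dn]]
        set.seed(derive_seed(seed, paste("calfit", dn, r, f)))
        m <- mlp_fit(pairs[tr, d[["inp"]]], pairs[tr, d[["out"]]],
                     hidden = hidden, maxit = maxit, n_starts = n_starts)
        pred <- predict(m, pairs[!tr, d[["inp"]]])
        pools[[dn]]$models[[k]] <- m
        pools[[dn]]$mse[k] <- mean((pred - pairs[!tr, d[["out"]]])^2)
      }
    }
  }

  sel <- lapply(pools, function(p) select_median_model(p$models, p$mse))
  # tie goes to the backward (Elecsys -> SiMoA) direction, the configuration
  # deployed when both calibrate equally well
  direction <- if (sel$forward$mse < sel$backward$mse) "simoa_to_elecsys" else "elecsys_to_simoa"
  chosen <- if (direction == "simoa_to_elecsys") sel$forward else sel$backward
  structure(list(direction = direction, selected = chosen$model,
                 selected_mse = chosen$mse,
                 mse_forward = sel$forward$mse, mse_backward = sel$backward$mse,
                 pools = list(forward = pools$forward$mse,
                              backward = pools$backward$mse),
                 pool_models = pools,
                 reference_platform = if (direction == "elecsys_to_simoa") "SiMoA" else "Elecsys",
                 rounds = as.integer(rounds), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "perisk_calibration")
}

#' Select the median-performance model from a pool
#'
#' Orders the pool by validation MSE (ascending) and returns the median-rank
#' element: rank `(n + 1) / 2` for odd pools, the lower-middle rank `n / 2`
#' for even pools (a single concrete model must be returned; the better of
#' the two middle models is kept). Ties keep the earliest pool index.
#'
#' @param models list of fitted models.
#' @param mse numeric vector of per-model validation MSEs.
#' @return list with `model`, `mse` and the original pool `index`.
#' @export
select_median_model <- function(models, mse) {
  n <- length(mse)
  if (n == 0L) stopf("empty model pool")
  if (length(models) != n) stopf("models and mse lengths differ")
  rank <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L
  target <- sort(mse)[rank]
  i <- which(mse == target)[1L]             # ties keep the earliest pool index
  list(model = models[[i]], mse = mse[i], index = i)
}

#' Calibrate PlGF values onto the reference platform scale
#'
#' Values measured on the reference platform pass through unchanged; values
#' from the other platform are mapped through the selected median network.
#'
#' @param plgf numeric vector of PlGF values (pg/mL), all positive.
#' @param platform `"SiMoA"`/`"Elecsys"`, scalar or one tag per value.
#' @param model a fitted [fit_calibrators()] result.
#' @return numeric vector on the reference scale, order and length preserved.
#' @export
calibrate <- function(plgf, platform, model) {
  stopifnot(inherits(model, "perisk_calibration"))
  platform <- as.character(platform)
  if (length(platform) == 1L) platform <- rep(platform, length(plgf))
  if (length(platform) != length(plgf)) stopf("platform and plgf lengths differ")
  ok <- is.na(platform) | platform %in% PLATFORM_LEVELS
  if (!all(ok)) stopf("unknown platform tag: %s", paste(unique(platform[!ok]), collapse = ", "))
  out <- plgf
  needs <- !is.na(plgf) & !is.na(platform) & platform != model$reference_platform
  if (any(needs)) out[needs] <- predict(model$selected, plgf[needs])
  out
}

#' Calibrate the PlGF column of a cohort table in place
#' @param table a cohort `data.frame` with `plgf` and `platform` columns.
#' @param model a fitted [fit_calibrators()] result.
#' @return the table with `plgf` on the reference scale and `platform` left
#'   untouched (it records where the value was measured).
#' @export
calibrate_cohort <- function(table, model) {
  table$plgf <- calibrate(table$plgf, as.character(table$platform), model)
  table
}

#' Write a JSON calibration report
#'
#' Records both directional MSE pools, the selected MSEs, the chosen
#' direction and the reference platform.
#'
#' @param model a `perisk_calibration`.
#' @param path JSON path.
#' @export
write_calibration_report <- function(model, path) {
  out <- list(direction = model$direction,
              reference_platform = model$reference_platform,
              mse_forward = model$mse_forward, mse_backward = model$mse_backward,
              selected_mse = model$selected_mse,
              rounds = model$rounds, folds = model$folds, seed = model$seed,
              pool_mse = model$pools)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
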