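#' Configure a risk classifier
#'
#' The primary algorithm is the random forest (`"rf"`); a neural network
#' (`"mlp"`), a linear soft-margin machine (`"svm"`), gradient boosting
#' (`"xgb"`) and AdaBoost (`"ada"`) are provided as comparators. Defaults for
#' the forest: 500 trees, unlimited depth (node size 1), `floor(sqrt(d))`
#' candidate features per split.
#'
#' @param algorithm one of `"rf"`, `"mlp"`, `"svm"`, `"xgb"`, `"ada"`.
#' @param hyperparameters named list overriding algorithm defaults:
#'   rf: `ntree`, `mtry`, `max_depth`, `min_bucket`;
#'   mlp: `hidden`, `decay`, `maxit`;
#'   svm: `cost`;
#'   xgb: `nrounds`, `eta`, `max_depth`, `lambda`;
#'   ada: `nrounds`, `max_depth`.
#' @param seed integer seed governing all stochastic fitting.
#' @param threshold decision cut on the risk score, strictly inside `(0, 1)`.
#' @return an object of class `perisk_predictor_config`.
#' @export
predictor_config <- function(algorithm = c("rf", "mlp", "svm", "xgb", "ada"),
                             hyperparameters = list(), seed = 0L,
                             threshold = 0.5) {
  algorithm <- match.arg(algorithm)
  if (threshold <= 0 || threshold >= 1) stopf("threshold must lie strictly inside (0, 1)")
  defaults <- switch(algorithm,
    rf = list(ntree = 500L, mtry = NULL, max_depth = 30L, min_bucket = 1L),
    mlp = list(hidden = 8L, decay = 0.01, maxit = 300L),
    svm = list(cost = 1),
    xgb = list(nrounds = 100L, eta = 0.1, max_depth = 3L, lambda = 1),
    ada = list(nrounds = 100L, max_depth = 1L))
  hp <- utils::modifyList(defaults, as.list(hyperparameters))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed), threshold = threshold),
            class = "perisk_predictor_config")
}

#' Train a risk prediction model
#'
#' Fits the configured classifier on a complete (imputed), normalized design
#' matrix. Every model exposes a continuous risk score in `[0, 1]`, so output
#' thresholding applies uniformly across algorithms.
#'
#' @param features a `perisk_encoded` object, or a plain numeric matrix.
#' @param config a [predictor_config()].
#' @param labels binary labels; defaults to the encoded object's own.
#' @return an object of class `perisk_risk_model`.
#' @export
train_model <- function(features, config = predictor_config(), labels = NULL) {
  x <- if (inherits(features, "perisk_encoded")) features$x else as.matrix(features)
  if (is.null(labels) && inherits(features, "perisk_encoded")) labels <- features$label
  if (is.null(labels)) stopf("labels are required")
  y <- as_label01(labels)
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
  if (anyNA(x)) stopf("missing entries in the feature matrix; impute upstream")
  hp <- config$hyperparameters
  set.seed(derive_seed(config$seed, paste("train", config$algorithm)))
  fit <- switch(config$algorithm,
                rf = rf_fit(x, y, hp),
                mlp = mlp_fit(x, y, hidden = hp$hidden, decay = hp$decay,
                              maxit = hp$maxit, logistic = TRUE),
                svm = svm_fit(x, y, hp),
                xgb = gbm_fit(x, y, hp),
                ada = ada_fit(x, y, hp))
  structure(list(algorithm = config$algorithm, fit = fit,
                 columns = colnames(x), config = config),
            class = "perisk_risk_model")
}

#' Predict PE risk scores and binary calls
#'
#' @param model a fitted [train_model()] result.
#' @param features a `perisk_encoded` object or numeric matrix with the
#'   training columns.
#' @param threshold decision cut; a record is called a case iff its score is
#'   `>=` the threshold. Defaults to the model's configured threshold.
#' @return list with `score` (numeric in `[0, 1]`) and `call` (factor with
#'   levels control/case).
#' @export
predict_risk <- function(model, features, threshold = model$config$threshold) {
  stopifnot(inherits(model, "perisk_risk_model"))
  x <- if (inherits(features, "perisk_encoded")) features$x else as.matrix(features)
  if (!identical(colnames(x), model$columns))
    stopf("feature columns do not match the training schema")
  if (anyNA(x)) stopf("missing entries in the feature matrix; impute upstream")
  score <- switch(model$algorithm,
                  rf = rf_predict(model$fit, x),
                  mlp = as.numeric(predict(model$fit, x)),
                  svm = svm_predict(model$fit, x),
                  xgb = gbm_predict(model$fit, x),
                  ada = ada_predict(model$fit, x))
  score <- pmin(pmax(score, 0), 1)
  list(score = score,
       call = factor(ifelse(score >= threshold, "case", "control"),
                     levels = c("control", "case")))
}

#' Rank features by forest importance
#'
#' Importance is the impurity decrease accumulated over all splits of all
#' trees, normalized to sum to 1 and sorted descending (ties keep column
#' order).
#'
#' @param model a fitted random-forest [train_model()] result.
#' @param feature_names optional names; defaults to the training columns.
#' @return named numeric vector of importance scores, descending.
#' @export
feature_importance <- function(model, feature_names = model$columns) {
  stopifnot(inherits(model, "perisk_risk_model"))
  if (model$algorithm != "rf")
    stopf("feature importance is only available for the random forest")
  imp <- model$fit$importance
  names(imp) <- feature_names
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp[order(-imp, seq_along(imp))]
}

## ---- tree ensembles over the CART engine --------------------------------

rf_fit <- function(x, y, hp) {
  n <- nrow(x); d <- ncol(x)
  mtry <- hp$mtry %||% max(1L, floor(sqrt(d)))
  trees <- vector("list", hp$ntree)
  importance <- numeric(d)
  for (t in seq_len(hp$ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    tr <- cart_grow(x[idx, , drop = FALSE], y[idx], rep(1, n), mtry,
                    hp$max_depth, 2L * hp$min_bucket, hp$min_bucket)
    importance <- importance + tr$importance
    trees[[t]] <- tr
  }
  list(trees = trees, importance = importance, mtry = mtry)
}

rf_predict <- function(fit, x) {
  s <- numeric(nrow(x))
  for (tr in fit$trees) s <- s + cart_predict(tr, x)
  s / length(fit$trees)
}

gbm_fit <- function(x, y, hp) {
  n <- nrow(x); d <- ncol(x)
  p0 <- mean(y)
  f0 <- log(p0 / (1 - p0))
  F <- rep(f0, n)
  trees <- vector("list", hp$nrounds)
  gammas <- vector("list", hp$nrounds)
  for (m in seq_len(hp$nrounds)) {
    p <- 1 / (1 + exp(-F))
    g <- y - p
    h <- p * (1 - p)
    tr <- cart_grow(x, g, rep(1, n), d, hp$max_depth, 10L, 5L)
    leaf <- cart_leaf(tr, x) + 1L
    # Newton step per terminal node with L2 regularisation on leaf values
    gamma <- vapply(seq_along(tr$value), function(node) {
      rows <- leaf == node
      if (!any(rows)) return(0)
      sum(g[rows]) / (sum(h[rows]) + hp$lambda)
    }, 0)
    F <- F + hp$eta * gamma[leaf]
    trees[[m]] <- tr; gammas[[m]] <- gamma
  }
  list(trees = trees, gammas = gammas, f0 = f0, eta = hp$eta)
}

gbm_predict <- function(fit, x) {
  F <- rep(fit$f0, nrow(x))
  for (m in seq_along(fit$trees))
    F <- F + fit$eta * fit$gammas[[m]][cart_leaf(fit$trees[[m]], x) + 1L]
  1 / (1 + exp(-F))
}

ada_fit <- function(x, y, hp) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(hp$nrounds)) {
    tr <- cart_grow(x, y, w, ncol(x), hp$max_depth, 2L, 1L)
    h <- as.integer(cart_predict(tr, x) >= 0.5)
    err <- sum(w[h != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (h != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(trees = trees, alphas = alphas)
}

ada_predict <- function(fit, x) {
  if (!length(fit$trees)) return(rep(0.5, nrow(x)))
  s <- numeric(nrow(x))
  for (m in seq_along(fit$trees))
    s <- s + fit$alphas[m] * as.numeric(cart_predict(fit$trees[[m]], x) >= 0.5)
  s / sum(fit$alphas)
}

## ---- linear soft-margin machine -----------------------------------------

# squared-hinge SVM fitted by BFGS; score is the logistic of the margin
svm_fit <- function(x, y, hp) {
  xc <- colMeans(x); xs <- apply(x, 2, sd); xs[xs < 1e-12] <- 1
  xz <- sweep(sweep(x, 2, xc), 2, xs, "/")
  yy <- 2 * y - 1
  d <- ncol(x)
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    m <- drop(xz %*% w) + b
    slack <- pmax(0, 1 - yy * m)
    sum(w^2) / 2 + hp$cost * sum(slack^2)
  }
  gr <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    m <- drop(xz %*% w) + b
    slack <- pmax(0, 1 - yy * m)
    gm <- -2 * hp$cost * slack * yy
    c(w + drop(crossprod(xz, gm)), sum(gm))
  }
  opt <- optim(rep(0, d + 1), obj, gr, method = "BFGS",
               control = list(maxit = 200L, reltol = 1e-10))
  list(w = opt$par[seq_len(d)], b = opt$par[d + 1], xc = xc, xs = xs)
}

svm_predict <- function(fit, x) {
  xz <- sweep(sweep(x, 2, fit$xc), 2, fit$xs, "/")
  1 / (1 + exp(-(drop(xz %*% fit$w) + fit$b)))
}

## ---- output-threshold optimisation --------------------------------------

#' Search the F1-optimal output threshold
#'
#' For each cross-validation round, out-of-fold risk scores are pooled and
#' the grid threshold maximizing F1 is recorded; ties break to the smallest
#' threshold (the most sensitive cut at equal F1). The search is summarized
#' as median +/- deviation (median absolute deviation about the median)
#' across rounds.
#'
#' @param table a cohort `data.frame` with labels.
#' @param config a [predictor_config()].
#' @param rounds,folds cross-validation shape.
#' @param grid grid step in `(0, 0.5]`; the grid is `seq(step, 1 - step,
#'   by = step)`.
#' @param seed integer seed.
#' @return an object of class `perisk_threshold_search`: list with
#'   `per_round_optima`, `median`, `deviation`, `criterion` and `grid`.
#' @export
optimize_threshold <- function(table, config = predictor_config(),
                               rounds = 10L, folds = 10L, grid = 0.01,
                               seed = 0L) {
  if (rounds < 1L) stopf("rounds must be >= 1")
  if (grid <= 0 || grid > 0.5) stopf("grid step must lie in (0, 0.5]")
  thr_grid <- seq(grid, 1 - grid, by = grid)
  optima <- numeric(rounds)
  for (r in seq_len(rounds)) {
    oof <- oof_scores(table, config, folds, derive_seed(seed, paste("thr round", r)))
    f1s <- vapply(thr_grid, function(t) f1_score(oof$labels, oof$scores, t), 0)
    optima[r] <- thr_grid[which.max(f1s)]   # first max = smallest threshold
  }
  structure(list(per_round_optima = optima, median = median(optima),
                 deviation = deviation_about_median(optima),
                 criterion = "F1", grid = thr_grid,
                 rounds = as.integer(rounds), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "perisk_threshold_search")
}
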