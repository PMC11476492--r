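#' Small multilayer perceptrons fitted by full-batch BFGS
#'
#' The pipeline leans on deliberately tiny networks: the relation models used
#' for dependent-pair imputation and the cross-platform PlGF calibrators are
#' all one-input/one-output regressors with a handful of sigmoidal hidden
#' units and a linear output, trained full-batch on standardized values. A
#' logistic-output variant serves as the neural-network comparator classifier.
#' Gradients are closed form and optimisation uses [stats::optim()] (BFGS),
#' so fits are deterministic under `set.seed()`.
#'
#' @param x numeric matrix (or vector, treated as one column) of inputs.
#' @param y numeric response; for `logistic = TRUE` must be 0/1.
#' @param hidden number of sigmoidal hidden units.
#' @param decay L2 weight penalty.
#' @param maxit BFGS iteration cap.
#' @param logistic if `TRUE` the output unit is logistic and the loss is
#'   cross-entropy; otherwise linear output and squared-error loss.
#' @param standardize z-score inputs (and, for regression, the target) before
#'   fitting and undo the transform at prediction time. Raw pg/mL scales are
#'   outside the useful range of a 2-unit sigmoid layer.
#' @param n_starts random restarts; the fit with the lowest penalized
#'   training loss is kept (BFGS on a tiny sigmoid network can stall in a
#'   shallow local optimum).
#' @return an object of class `perisk_mlp` with a `predict()` method.
#' @keywords internal
mlp_fit <- function(x, y, hidden = 2L, decay = 0, maxit = 500L,
                    logistic = FALSE, standardize = TRUE, n_starts = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x); h <- as.integer(hidden)
  if (n < 2L) stopf("mlp_fit: need at least 2 rows, got %d", n)
  if (anyNA(x) || anyNA(y)) stopf("mlp_fit: missing values in training data")

  xc <- rep(0, p); xs <- rep(1, p); yc <- 0; ys <- 1
  if (standardize) {
    xc <- colMeans(x); xs <- apply(x, 2, sd); xs[xs < 1e-12] <- 1
    x <- sweep(sweep(x, 2, xc), 2, xs, "/")
    if (!logistic) {
      yc <- mean(y); ys <- sd(y); if (!is.finite(ys) || ys < 1e-12) ys <- 1
      y <- (y - yc) / ys
    }
  }

  n_w1 <- (p + 1L) * h            # input->hidden incl. bias
  n_w2 <- h + 1L                  # hidden->output incl. bias
  unpack <- function(theta) {
    list(W1 = matrix(theta[seq_len(n_w1)], p + 1L, h),
         W2 = theta[n_w1 + seq_len(n_w2)])
  }
  X1 <- cbind(1, x)
  sigm <- function(z) 1 / (1 + exp(-z))

  fwd <- function(theta) {
    w <- unpack(theta)
    Z <- sigm(X1 %*% w$W1)          # n x h
    o <- drop(cbind(1, Z) %*% w$W2) # n
    list(Z = Z, o = if (logistic) sigm(o) else o, w = w)
  }
  loss <- function(theta) {
    f <- fwd(theta)
    fit <- if (logistic) {
      eps <- 1e-12
      -sum(y * log(f$o + eps) + (1 - y) * log(1 - f$o + eps))
    } else sum((f$o - y)^2) / 2
    fit + decay * sum(theta^2) / 2
  }
  grad <- function(theta) {
    f <- fwd(theta)
    delta_o <- f$o - y              # same form for both losses
    gW2 <- drop(crossprod(cbind(1, f$Z), delta_o))
    delta_h <- (delta_o %*% t(f$w$W2[-1])) * f$Z * (1 - f$Z)
    gW1 <- crossprod(X1, delta_h)
    c(as.vector(gW1), gW2) + decay * theta
  }

  opt <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    theta0 <- runif(n_w1 + n_w2, -0.7, 0.7)
    o <- optim(theta0, loss, grad, method = "BFGS",
               control = list(maxit = as.integer(maxit), reltol = 1e-12))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  structure(list(theta = opt$par, p = p, hidden = h, logistic = logistic,
                 xc = xc, xs = xs, yc = yc, ys = ys, value = opt$value,
                 n = n),
            class = "perisk_mlp")
}

#' @export
predict.perisk_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$p) stopf("mlp predict: expected %d columns", object$p)
  x <- sweep(sweep(x, 2, object$xc), 2, object$xs, "/")
  p <- object$p; h <- object$hidden
  W1 <- matrix(object$theta[seq_len((p + 1L) * h)], p + 1L, h)
  W2 <- object$theta[(p + 1L) * h + seq_len(h + 1L)]
  Z <- 1 / (1 + exp(-(cbind(1, x) %*% W1)))
  o <- drop(cbind(1, Z) %*% W2)
  if (object$logistic) 1 / (1 + exp(-o)) else o * object$ys + object$yc
}
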