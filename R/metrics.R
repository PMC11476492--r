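#' Classification metrics for imbalanced risk prediction
#'
#' All threshold-dependent quantities derive from the confusion matrix at the
#' given cut (a record is called positive iff its score is >= the threshold):
#' error rate, TPR (sensitivity/recall), FPR, TNR = 1 - FPR, FNR = 1 - TPR,
#' precision and F1 (harmonic mean of precision and recall). AUC_ROC is the
#' threshold-free Mann-Whitney statistic (ties count 1/2); AUC_PRC is average
#' precision (step-wise, no interpolation between operating points).
#'
#' @param labels binary labels: a factor with levels control/case, or 0/1
#'   (1 = case).
#' @param scores numeric risk scores in `[0, 1]`.
#' @param threshold decision cut in `(0, 1)`.
#' @return an object of class `perisk_metrics`: a list with `error_rate`,
#'   `tpr`, `fpr`, `tnr`, `fnr`, `precision`, `f1`, `micro_f1`, `macro_f1`,
#'   `auc_roc`, `auc_prc`, and confusion counts `tp`, `fp`, `tn`, `fn`, `n`.
#'   With single-class labels the AUCs are `NaN` with a warning.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), threshold = 0.5)
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as_label01(labels)
  if (length(y) != length(scores) || length(y) == 0L)
    stopf("labels and scores must be non-empty and of equal length")
  call <- scores >= threshold
  tp <- sum(call & y == 1); fp <- sum(call & y == 0)
  fn <- sum(!call & y == 1); tn <- sum(!call & y == 0)
  n <- length(y)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NaN
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NaN
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  if (length(unique(y)) < 2L) {
    warnf("single-class labels: AUCs undefined")
    auc_roc <- auc_prc <- NaN
  } else {
    auc_roc <- auc_roc_stat(y, scores)
    auc_prc <- average_precision(y, scores)
  }
  structure(list(error_rate = (fp + fn) / n, tpr = tpr, fpr = fpr,
                 tnr = 1 - fpr, fnr = 1 - tpr, precision = precision,
                 f1 = f1, micro_f1 = f1, macro_f1 = f1,
                 auc_roc = auc_roc, auc_prc = auc_prc,
                 tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 threshold = threshold),
            class = "perisk_metrics")
}

as_label01 <- function(labels) {
  if (is.factor(labels)) {
    lv <- levels(labels)
    if (all(c("control", "case") %in% lv)) return(as.integer(labels == "case"))
    if (length(lv) > 2L) stopf("labels must be binary")
    return(as.integer(labels) - 1L)
  }
  v <- as.numeric(labels)
  if (!all(v %in% c(0, 1))) stopf("labels must be binary 0/1 or control/case")
  as.integer(v)
}

# Mann-Whitney AUC with tie correction
auc_roc_stat <- function(y, scores) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision over descending-score thresholds; tied scores form a
# single operating point
average_precision <- function(y, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  boundary <- c(s[-length(s)] != s[-1], TRUE)  # last row of each tie group
  tp <- cumsum(y)[boundary]
  pred_pos <- seq_along(y)[boundary]
  npos <- sum(y)
  recall <- tp / npos
  precision <- tp / pred_pos
  sum(diff(c(0, recall)) * precision)
}

#' F1 score from labels, scores and a threshold
#' @inheritParams compute_metrics
#' @return the F1 of the positive (case) class.
#' @export
f1_score <- function(labels, scores, threshold = 0.5) {
  y <- as_label01(labels)
  call <- scores >= threshold
  tp <- sum(call & y == 1); fp <- sum(call & y == 0); fn <- sum(!call & y == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# deviation statistic used throughout the reports: the median absolute
# deviation about the median, without a consistency constant
deviation_about_median <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NaN)
  median(abs(x - median(x)))
}
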