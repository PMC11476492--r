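#' Configure minority-class oversampling
#'
#' Interpolation-based synthetic minority oversampling, plain (`"smote"`)
#' or cluster-aware (`"kmeans_smote"`, the variant adopted for the
#' augmentation experiments). The minority class is augmented until its count
#' reaches `round(target_ratio * majority count)`; the study's ratio of 1.2
#' cases to controls is the default, read literally (cases overshoot
#' controls).
#'
#' Other published oversamplers (Borderline, ADASYN, SMOTENC, SVM-SMOTE) are
#' accepted through the function-augmenter interface of
#' [augmented_real_test_cv()] rather than re-implemented.
#'
#' @param method `"kmeans_smote"` or `"smote"`.
#' @param target_ratio desired minority/majority ratio after augmentation;
#'   must exceed the existing ratio.
#' @param k_neighbors neighbours considered for interpolation (plain SMOTE).
#' @param n_clusters clusters for the cluster-aware variant; default
#'   `round(sqrt(minority n))`.
#' @param seed integer seed.
#' @return an object of class `perisk_augmentation_config`.
#' @export
augmentation_config <- function(method = c("kmeans_smote", "smote"),
                                target_ratio = 1.2, k_neighbors = 5L,
                                n_clusters = NULL, seed = 0L) {
  method <- match.arg(method)
  if (k_neighbors < 1L) stopf("k_neighbors must be >= 1")
  if (target_ratio <= 0) stopf("target_ratio must be positive")
  structure(list(method = method, target_ratio = target_ratio,
                 k_neighbors = as.integer(k_neighbors),
                 n_clusters = n_clusters, seed = as.integer(seed)),
            class = "perisk_augmentation_config")
}

#' Oversample the minority class by interpolation
#'
#' Synthetic minority rows are convex combinations of existing minority rows:
#' a random minority record and one of its `k` nearest minority neighbours
#' (plain variant), or two minority records from the same k-means cluster
#' (cluster-aware variant). Majority rows are untouched; original rows appear
#' first, in order, followed by the synthetic rows, and every synthetic row
#' is flagged.
#'
#' @param x complete numeric feature matrix.
#' @param labels binary labels (factor control/case or 0/1).
#' @param config an [augmentation_config()].
#' @return list with `x` (augmented matrix), `labels` and `origin`
#'   (`"real"`/`"synthetic"`).
#' @export
augment <- function(x, labels, config = augmentation_config()) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("augment requires a complete matrix; impute first")
  y <- as_label01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  n_after <- round(config$target_ratio * n_maj)
  if (n_after <= n_min)
    stopf("target_ratio %.3g does not exceed the existing minority/majority ratio %.3g",
          config$target_ratio, n_min / n_maj)
  n_new <- n_after - n_min
  rows <- which(y == minority)
  xm <- x[rows, , drop = FALSE]

  set.seed(derive_seed(config$seed, "augment"))
  syn <- if (config$method == "smote") {
    smote_rows(xm, n_new, config$k_neighbors)
  } else {
    kmeans_smote_rows(xm, n_new, config$n_clusters)
  }
  out_x <- rbind(x, syn)
  lab_lv <- if (is.factor(labels)) labels else factor(ifelse(y == 1, "case", "control"),
                                                     levels = c("control", "case"))
  minority_label <- if (minority == 1L) "case" else "control"
  list(x = out_x,
       labels = factor(c(as.character(lab_lv), rep(minority_label, n_new)),
                       levels = levels(lab_lv)),
       origin = c(rep("real", nrow(x)), rep("synthetic", n_new)))
}

smote_rows <- function(xm, n_new, k) {
  n <- nrow(xm)
  if (n == 1L) return(xm[rep(1L, n_new), , drop = FALSE])
  if (k > n - 1L) {
    warnf("k_neighbors reduced from %d to %d (minority size)", k, n - 1L)
    k <- n - 1L
  }
  d2 <- as.matrix(dist(xm))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  base <- sample.int(n, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- runif(n_new)
  xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
}

kmeans_smote_rows <- function(xm, n_new, n_clusters) {
  n <- nrow(xm)
  n_distinct <- nrow(unique(xm))
  if (n_distinct == 1L) return(xm[rep(1L, n_new), , drop = FALSE])
  kc <- n_clusters %||% max(1L, round(sqrt(n)))
  kc <- min(kc, n_distinct)
  cl <- kmeans(xm, centers = kc, nstart = 1L)$cluster
  sizes <- tabulate(cl, kc)
  pick_cluster <- sample.int(kc, n_new, replace = TRUE, prob = sizes / n)
  syn <- matrix(NA_real_, n_new, ncol(xm), dimnames = list(NULL, colnames(xm)))
  for (i in seq_len(n_new)) {
    members <- which(cl == pick_cluster[i])
    a <- members[sample.int(length(members), 1L)]
    b <- if (length(members) == 1L) a else {
      others <- setdiff(members, a)
      others[sample.int(length(others), 1L)]
    }
    u <- runif(1)
    syn[i, ] <- xm[a, ] + u * (xm[b, ] - xm[a, ])
  }
  syn
}
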