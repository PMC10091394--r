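#' @name classify
#' @title Subtype classifiers and their evaluation
#' @description Random-forest classification of the hybrid subtype from
#'   GDTEC or fold-change features, Gini-importance feature selection,
#'   ROC/AUC evaluation, the external copy-number-fraction labeling rule,
#'   and k-nearest-neighbor label transfer to external cohorts.
NULL

#' Train a random-forest subtype classifier
#'
#' Stratified train/test split (per-class sampling at `train_fraction`),
#' a fixed-seed forest, mean-decrease-in-Gini importances and held-out
#' scores. Fully reproducible given the seed.
#'
#' @param features Matrix or data frame, samples as rows, features as
#'   columns (binary GDTEC indicators or real fold changes).
#' @param labels Two-level factor over the samples; `positive` defaults to
#'   the second level.
#' @param train_fraction Fraction of each class used for training
#'   (default 0.7).
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param seed Integer seed controlling the split and the forest.
#' @param positive Name of the positive class.
#' @return An object of class `"gdtec_rf"`: the forest, `importance`
#'   (MeanDecreaseGini), a held-out `test` table (truth, score in \[0, 1\],
#'   predicted label at the 0.5 score threshold), `accuracy`, `roc`
#'   ([roc_auc()] result on the held-out scores), and the split IDs.
#' @export
train_rf <- function(features, labels, train_fraction = 0.7, ntree = 500,
                     mtry = NULL, seed = 1L, positive = NULL) {
  features <- as.data.frame(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    gd_stop("gdtec_config_error", "labels must have exactly two classes")
  }
  if (length(labels) != nrow(features)) {
    gd_stop("gdtec_alignment_error", "labels must cover every sample row")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    gd_stop("gdtec_config_error", "train_fraction must be in (0, 1)")
  }
  positive <- positive %||% levels(labels)[2]
  if (!positive %in% levels(labels)) {
    gd_stop("gdtec_config_error", "positive class '%s' not among labels", positive)
  }
  colnames(features) <- make.names(colnames(features))
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(levels(labels), function(l) {
    idx <- which(labels == l)
    sample(idx, max(1L, floor(train_fraction * length(idx))))
  }))
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(features)), train_idx)
  if (length(unique(labels[train_idx])) < 2L || length(test_idx) == 0L) {
    gd_stop("gdtec_degenerate_error", "split left a single-class training set or empty test set")
  }
  rf <- randomForest::randomForest(
    x = features[train_idx, , drop = FALSE], y = labels[train_idx],
    ntree = ntree, mtry = mtry %||% max(1L, floor(sqrt(ncol(features)))))
  importance <- setNames(rf$importance[, "MeanDecreaseGini"],
                         rownames(rf$importance))
  scores <- predict(rf, features[test_idx, , drop = FALSE],
                    type = "prob")[, positive]
  truth <- labels[test_idx]
  negative <- setdiff(levels(labels), positive)
  pred <- factor(ifelse(scores > 0.5, positive, negative), levels = levels(labels))
  roc <- if (length(unique(truth)) == 2L) {
    roc_auc(scores, as.integer(truth == positive))
  } else NULL
  structure(list(forest = rf, importance = importance,
                 test = data.frame(sample = rownames(features)[test_idx],
                                   truth = truth, score = unname(scores),
                                   pred = pred, stringsAsFactors = FALSE),
                 accuracy = mean(pred == truth), roc = roc,
                 train_ids = rownames(features)[train_idx],
                 test_ids = rownames(features)[test_idx],
                 positive = positive, seed = as.integer(seed),
                 ntree = ntree),
            class = "gdtec_rf")
}

#' @export
print.gdtec_rf <- function(x, ...) {
  cat(sprintf("Random-forest subtype classifier (%d trees, seed %d)\n",
              x$ntree, x$seed))
  cat(sprintf("held-out: n = %d, accuracy = %.3f%s\n",
              nrow(x$test), x$accuracy,
              if (!is.null(x$roc)) sprintf(", AUC = %.3f", x$roc$auc) else ""))
  cat("top features by MeanDecreaseGini:\n")
  print(head(sort(x$importance, decreasing = TRUE), 5))
  invisible(x)
}

#' Select features by Gini importance
#'
#' Threshold mode keeps features with importance strictly greater than
#' `threshold`; `top_n` keeps the n largest (ties broken by feature ID
#' order). When both are given, `top_n` takes precedence (with a message).
#'
#' @param fit A `"gdtec_rf"` object or a named importance vector.
#' @param threshold Strict lower bound on MeanDecreaseGini.
#' @param top_n Number of features to keep.
#' @return Character vector of selected feature IDs.
#' @export
gini_select <- function(fit, threshold = NULL, top_n = NULL) {
  imp <- if (inherits(fit, "gdtec_rf")) fit$importance else fit
  if (is.null(names(imp))) gd_stop("gdtec_config_error", "importances must be named")
  if (is.null(threshold) && is.null(top_n)) {
    gd_stop("gdtec_config_error", "supply threshold or top_n")
  }
  if (!is.null(top_n)) {
    if (!is.null(threshold)) message("both threshold and top_n given; using top_n")
    if (top_n > length(imp)) {
      warning("top_n exceeds feature count; returning all features")
      top_n <- length(imp)
    }
    ord <- order(-imp, names(imp))
    return(names(imp)[ord][seq_len(top_n)])
  }
  names(imp)[imp > threshold]
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability (ties counted one
#' half); the stored curve is the threshold sweep whose trapezoidal area
#' equals the AUC. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Real classification scores, larger meaning more positive.
#' @param labels Binary labels (0/1, logical, or two-level factor whose
#'   second level is positive).
#' @return An object of class `"roc_result"`: `points` (data frame of
#'   false- and true-positive rates, monotone in both coordinates) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    gd_stop("gdtec_domain_error", "labels must be binary")
  }
  if (length(unique(labels)) < 2L) {
    gd_stop("gdtec_degenerate_error", "both classes must be present")
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  points <- data.frame(fpr = (1 - r$specificities)[ord],
                       tpr = r$sensitivities[ord])
  structure(list(points = points, auc = as.numeric(pROC::auc(r))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d curve points\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "false-positive rate", ylab = "true-positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Label an external cohort by copy-number fraction over marker genes
#'
#' A patient is labeled `Mix_Sub` when strictly more than `min_fraction`
#' of the marker genes present in the matrix carry a nonzero copy-number
#' call (any depth); exactly at the bound is `non-Mix_Sub`.
#'
#' @param cnv_calls Integer-call or ternary gene-by-sample matrix.
#' @param marker_genes Character vector of marker gene IDs; at least one
#'   must be present in the matrix.
#' @param min_fraction Strict lower bound (default 0.8).
#' @return Named factor with levels `non-Mix_Sub`, `Mix_Sub`; the per-sample
#'   fractions are carried in attribute `"fraction"`.
#' @export
cnv_rule_label <- function(cnv_calls, marker_genes, min_fraction = 0.8) {
  present <- intersect(marker_genes, rownames(cnv_calls))
  if (length(present) == 0L) {
    gd_stop("gdtec_lookup_error", "no marker genes present in the CNV matrix")
  }
  frac <- colMeans(cnv_calls[present, , drop = FALSE] != 0)
  out <- factor(ifelse(frac > min_fraction, "Mix_Sub", "non-Mix_Sub"),
                levels = c("non-Mix_Sub", "Mix_Sub"))
  names(out) <- colnames(cnv_calls)
  attr(out, "fraction") <- frac
  attr(out, "markers_used") <- present
  out
}

.knn_dist <- function(test_x, train_x, distance) {
  if (distance == "euclidean") {
    cross <- tcrossprod(test_x, train_x)
    d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") - 2 * cross
    sqrt(pmax(d2, 0))
  } else {
    inter <- tcrossprod(test_x, train_x)
    union <- outer(rowSums(test_x), rowSums(train_x), "+") - inter
    d <- 1 - inter / union
    d[union == 0] <- 0  # two all-zero binary vectors are identical
    d
  }
}

#' Transfer class labels by k-nearest neighbors
#'
#' Majority vote among the k nearest training samples; vote ties are broken
#' deterministically by the smallest mean distance to the tied class's
#' voters. `k` must be odd (which rules out binary vote ties).
#'
#' @param train_features,test_features Matrices with samples as rows over
#'   the same feature space.
#' @param train_labels Factor over the training samples.
#' @param k Odd neighborhood size, at most the training size (default 5).
#' @param distance `"euclidean"` or `"jaccard"` (for binary features).
#' @return Factor of predicted labels for the test samples.
#' @export
knn_transfer <- function(train_features, train_labels, test_features, k = 5,
                         distance = c("euclidean", "jaccard")) {
  distance <- match.arg(distance)
  train_x <- as.matrix(train_features)
  test_x <- as.matrix(test_features)
  if (ncol(train_x) != ncol(test_x)) {
    gd_stop("gdtec_alignment_error", "train and test feature spaces differ")
  }
  train_labels <- droplevels(as.factor(train_labels))
  if (length(train_labels) != nrow(train_x)) {
    gd_stop("gdtec_alignment_error", "labels must cover every training sample")
  }
  if (k %% 2 == 0) gd_stop("gdtec_config_error", "k must be odd")
  if (k > nrow(train_x)) gd_stop("gdtec_config_error", "k exceeds training size")
  D <- .knn_dist(test_x, train_x, distance)
  pred <- apply(D, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      means <- vapply(top, function(l) mean(d[nn][train_labels[nn] == l]),
                      numeric(1))
      top <- top[order(means, top)][1]
    }
    top
  })
  out <- factor(pred, levels = levels(train_labels))
  names(out) <- rownames(test_x)
  out
}
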