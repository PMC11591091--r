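#' Multi-class confusion matrix
#'
#' Counts with true classes in rows and predicted classes in columns, over
#' the full declared class set.
#'
#' @param y_true,y_pred class labels (coerced to a common factor).
#' @param levels optional explicit class levels.
#' @return integer matrix (classes x classes).
#' @export
confusion_matrix <- function(y_true, y_pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(y_true),
                                               as.character(y_pred))))
  t_ <- factor(as.character(y_true), levels = levels)
  p_ <- factor(as.character(y_pred), levels = levels)
  as.matrix(table(true = t_, predicted = p_))
}

#' Macro-averaged classification metrics
#'
#' Accuracy is total true positives over total samples; macro-precision and
#' macro-recall average per-class `TP/(TP+FP)` and `TP/(TP+FN)` with equal
#' class weight; macro-F1 is the harmonic mean of the two macro averages.
#' The accounting identity `sum(TP+FN) = sum(TP+FP) = n` is asserted on
#' every call. A class absent from the true labels makes recall undefined
#' and raises an error rather than propagating NaN.
#'
#' @param cm confusion matrix from [confusion_matrix()], or `y_true` if
#'   `y_pred` is given.
#' @param y_pred optional predicted labels (then `cm` is taken as `y_true`).
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `per_class` (data frame of TP/FP/FN, precision, recall)
#'   and `confusion`.
#' @export
classification_metrics <- function(cm, y_pred = NULL) {
  if (!is.null(y_pred)) cm <- confusion_matrix(cm, y_pred)
  cm <- as.matrix(cm)
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  stopifnot(sum(tp + fn) == n, sum(tp + fp) == n)
  if (any(rowSums(cm) == 0))
    dk_stop("dk_undefined_recall",
            "class '%s' absent from the true labels: recall undefined",
            rownames(cm)[rowSums(cm) == 0][1])
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- tp / (tp + fn)
  macro_p <- mean(precision)
  macro_r <- mean(recall)
  list(accuracy = sum(tp) / n,
       macro_precision = macro_p,
       macro_recall = macro_r,
       macro_f1 = if (macro_p + macro_r == 0) 0 else
         2 * macro_p * macro_r / (macro_p + macro_r),
       per_class = data.frame(class = rownames(cm), tp = tp, fp = fp, fn = fn,
                              precision = precision, recall = recall),
       confusion = cm)
}

# one-vs-rest ROC curve for one class: step curve over score thresholds
ovr_roc <- function(score, is_pos) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  # collapse ties on the score
  keep <- c(diff(score[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep]) / sum(is_pos)
  fpr <- c(0, fp[keep]) / sum(!is_pos)
  list(fpr = fpr, tpr = tpr)
}

#' Macro-averaged one-vs-rest ROC curve and AUC
#'
#' Per class, the one-vs-rest ROC curve of that class's probability score is
#' interpolated onto a common FPR grid; curves are averaged with equal class
#' weight and the AUC taken by the trapezoid rule on the averaged curve.
#'
#' @param prob samples x classes probability matrix (columns named by class).
#' @param y_true true labels.
#' @param grid_points number of FPR grid points (default 101).
#' @return list with `fpr`, `tpr` (averaged curve), `auc`, `per_class_auc`.
#' @export
macro_roc <- function(prob, y_true, grid_points = 101) {
  classes <- colnames(prob)
  y <- as.character(y_true)
  grid <- seq(0, 1, length.out = grid_points)
  tprs <- matrix(NA_real_, grid_points, length(classes))
  aucs <- numeric(length(classes))
  for (j in seq_along(classes)) {
    pos <- y == classes[j]
    if (!any(pos) || all(pos))
      dk_stop("dk_undefined_recall", "class '%s' has no positives or no negatives",
              classes[j])
    rc <- ovr_roc(prob[, j], pos)
    tprs[, j] <- stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max,
                               rule = 2)$y
    aucs[j] <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  }
  tpr_avg <- rowMeans(tprs)
  auc <- sum(diff(grid) * (utils::head(tpr_avg, -1) + utils::tail(tpr_avg, -1)) / 2)
  list(fpr = grid, tpr = tpr_avg, auc = auc,
       per_class_auc = stats::setNames(aucs, classes))
}
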