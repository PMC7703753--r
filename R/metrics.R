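#' Balanced accuracy
#'
#' Unweighted mean of per-class recall for binary labels: the accuracy of
#' each class is evaluated separately and averaged, so the score is not
#' inflated by class imbalance. On a class-balanced dataset it equals plain
#' accuracy.
#'
#' @param y_true,y_pred 0/1 vectors of equal length; `y_true` must contain
#'   both classes.
#' @return a real in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(unique(y_true)) < 2) {
    stop("y_true must contain both classes for balanced accuracy")
  }
  r0 <- mean(y_pred[y_true == 0] == 0)
  r1 <- mean(y_pred[y_true == 1] == 1)
  (r0 + r1) / 2
}

# ROC AUC as the Mann-Whitney rank statistic; tied scores contribute 1/2.
roc_auc_score <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("ROC AUC needs both classes")
  r <- rank(y_score)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# PR AUC as step-wise average precision (no trapezoidal interpolation):
# AP = sum_k (R_k - R_{k-1}) * P_k over descending unique score thresholds.
pr_auc_score <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  if (sum(y_true == 1) == 0) stop("PR AUC needs positive examples")
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_score[ord]
  yt <- y_true[ord]
  tp <- cumsum(yt)
  fp <- cumsum(1 - yt)
  # threshold boundaries: last index of each tied score block
  last <- which(c(ys[-length(ys)] != ys[-1], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(yt)
  sum(diff(c(0, rec)) * prec)
}

#' Classification metric report
#'
#' Computes balanced accuracy, precision, recall, ROC AUC (Mann-Whitney rank
#' statistic, ties counting one half), PR AUC (step-wise average precision)
#' and the confusion matrix (rows = true class, columns = predicted class)
#' for hard predictions plus a class-1 score vector.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @param y_score real-valued class-1 scores (higher = more class 1).
#' @return an object of class `metric_report`: a list with
#'   `balanced_accuracy`, `precision`, `recall`, `roc_auc`, `pr_auc`,
#'   `confusion` (2x2 counts) and `confusion_normalized` (row-normalized).
#' @export
classification_report <- function(y_true, y_pred, y_score) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (sum(y_true == 1) == 0) {
    stop("no positive examples: precision/recall undefined")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  conf <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                 dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  structure(
    list(balanced_accuracy = balanced_accuracy(y_true, y_pred),
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = tp / (tp + fn),
         roc_auc = roc_auc_score(y_true, y_score),
         pr_auc = pr_auc_score(y_true, y_score),
         confusion = conf,
         confusion_normalized = conf / pmax(rowSums(conf), 1)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<metric_report> bal_acc=%.*f precision=%.*f recall=%.*f roc_auc=%.*f pr_auc=%.*f\n",
    digits, x$balanced_accuracy, digits, x$precision, digits, x$recall,
    digits, x$roc_auc, digits, x$pr_auc))
  invisible(x)
}
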