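#' Confusion counts for binary predictions
#'
#' Positive class = ACP (label 1).
#'
#' @param truth,predicted equal-length binary (0/1) vectors.
#' @return object of class `confusion_counts` with fields tp, tn, fp, fn.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be binary 0/1")
  structure(list(tp = sum(truth == 1 & predicted == 1),
                 tn = sum(truth == 0 & predicted == 0),
                 fp = sum(truth == 0 & predicted == 1),
                 fn = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' Build confusion counts from the four cells
#' @param tp,tn,fp,fn non-negative integers.
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/N, F1 = 2TP/(2TP+FP+FN), Recall = TP/(TP+FN),
#' Precision = TP/(TP+FP), and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A zero factor under the MCC square root (or a zero precision/recall
#' denominator) yields 0 with `degenerate = TRUE` rather than an error, the
#' standard convention that keeps batch evaluation alive.
#'
#' @param counts a `confusion_counts` object.
#' @return list with accuracy, f1, recall, precision (proportions in [0,1]),
#'   mcc in [-1,1], counts, and a `degenerate` flag.
#' @examples
#' m <- metrics_from_counts(confusion_counts(tp = 72, tn = 75, fp = 7, fn = 10))
#' round(100 * m$accuracy, 1)  # 89.6
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion table")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  mcc_den <- prod(c(tp + fn, tp + fp, tn + fp, tn + fn))
  mcc <- if (mcc_den == 0) { degenerate <- TRUE; 0 }
         else (tp * tn - fp * fn) / sqrt(mcc_den)
  list(accuracy = (tp + tn) / n,
       f1 = safe_div(2 * tp, 2 * tp + fp + fn),
       recall = safe_div(tp, tp + fn),
       precision = safe_div(tp, tp + fp),
       mcc = mcc,
       counts = counts,
       degenerate = degenerate)
}

## Shared threshold sweep: rows ordered by decreasing score, tied scores
## collapsed into one operating point.
threshold_sweep <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  list(tp = c(0, tp[last]), fp = c(0, fp[last]),
       n_pos = sum(truth == 1), n_neg = sum(truth == 0))
}

#' ROC curve and AUC
#'
#' Curve points over all score thresholds; AUC by trapezoidal integration,
#' equivalent to the rank-average (Mann-Whitney) treatment of tied scores.
#'
#' @param scores numeric prediction scores.
#' @param truth binary 0/1 labels.
#' @return list with `curve` (data.frame fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  sw <- threshold_sweep(scores, truth)
  if (sw$n_pos == 0 || sw$n_neg == 0)
    stop("ROC requires both classes present")
  tpr <- sw$tp / sw$n_pos
  fpr <- sw$fp / sw$n_neg
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and area
#'
#' Area by the average-precision step convention: AP = sum over operating
#' points of (recall step) * precision, which differs slightly from
#' trapezoidal PR integration and is the convention documented here.
#'
#' @param scores numeric prediction scores.
#' @param truth binary 0/1 labels.
#' @return list with `curve` (data.frame recall, precision) and `prauc`.
#' @export
pr_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  sw <- threshold_sweep(scores, truth)
  if (sw$n_pos == 0) stop("PR curve requires at least one positive")
  tp <- sw$tp[-1]; fp <- sw$fp[-1]
  recall <- tp / sw$n_pos
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = c(0, recall),
                          precision = c(1, precision)),
       prauc = ap)
}

#' Evaluate a trained model on a labeled dataset
#'
#' Scores every peptide, thresholds the scores (strict `>`), and reports the
#' full metric set: accuracy, F1, recall, precision, MCC, AUC, PRAUC, and the
#' confusion counts.
#'
#' @param model a trained model from [acpnet_train()].
#' @param dataset labeled `peptide_set`.
#' @param threshold decision threshold, default 0.5.
#' @return a `metrics_report` list.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5) {
  stopifnot(inherits(dataset, "peptide_set"))
  preds <- predict(model, dataset, threshold = threshold)
  metrics_report(dataset$label, preds$score, threshold)
}

#' Metrics report from scores and truth labels
#'
#' @param truth binary 0/1 labels.
#' @param scores prediction scores in [0,1].
#' @param threshold decision threshold (strict `>`).
#' @return list of class `metrics_report`: threshold, counts, the five
#'   confusion metrics, auc, prauc.
#' @export
metrics_report <- function(truth, scores, threshold = 0.5) {
  predicted <- as.integer(scores > threshold)
  cc <- confusion(truth, predicted)
  m <- metrics_from_counts(cc)
  m$auc <- roc_auc(scores, truth)$auc
  m$prauc <- pr_auc(scores, truth)$prauc
  m$threshold <- threshold
  class(m) <- "metrics_report"
  m
}

#' @export
print.metrics_report <- function(x, ...) {
  cc <- x$counts
  cat(sprintf("confusion (threshold %g): TP=%d TN=%d FP=%d FN=%d\n",
              x$threshold, cc$tp, cc$tn, cc$fp, cc$fn))
  cat(sprintf(
    "accuracy %.1f%%  F1 %.1f%%  recall %.1f%%  precision %.1f%%\n",
    100 * x$accuracy, 100 * x$f1, 100 * x$recall, 100 * x$precision))
  cat(sprintf("MCC %.3f  AUC %.3f  PRAUC %.3f\n", x$mcc, x$auc, x$prauc))
  invisible(x)
}
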