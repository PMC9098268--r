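#' Classification performance metrics
#'
#' Sensitivity (TP/(TP+FN)), specificity (TN/(TN+FP)) and accuracy
#' ((TP+TN)/total) as percentages rounded to two decimals, with patients
#' (label 1) as the positive class, plus the area under the empirical ROC
#' curve computed by the Mann-Whitney statistic (tied scores contribute 1/2),
#' which equals trapezoidal integration of the ROC. If the truth contains a
#' single class, the undefined rate is returned as `NA` (flagged missing, not
#' zero).
#'
#' @param truth binary true labels (1 = patient/case).
#' @param pred binary predicted labels.
#' @param scores continuous class-1 tendencies for the AUC (optional; without
#'   scores `auc` is `NA`).
#' @return list: `sensitivity`, `specificity`, `accuracy` (percent), `auc`,
#'   and the confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1), c(0.9, 0.4, 0.2, 0.6))
compute_metrics <- function(truth, pred, scores = NULL) {
  truth <- as_binary_labels(truth)
  pred <- as_binary_labels(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == 1 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  pct <- function(num, den) if (den == 0) NA_real_ else
    round(100 * num / den, 2)
  list(sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp),
       accuracy = pct(tp + tn, length(truth)),
       auc = if (is.null(scores)) NA_real_ else auc_mann_whitney(truth,
                                                                 scores),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' `AUC = P(score_case > score_control) + 0.5 P(equal)`, computed from rank
#' sums; equals the trapezoidal area under the empirical ROC curve.
#'
#' @param truth binary labels (1 = positive).
#' @param scores continuous scores, larger = more case-like.
#' @return AUC in `[0, 1]`, or `NA` if the truth has a single class.
#' @export
auc_mann_whitney <- function(truth, scores) {
  truth <- as_binary_labels(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
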