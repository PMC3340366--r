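#' Classification and regression metrics
#'
#' Confusion-count based scores with the methylated state as positive
#' class. MCC follows the 0/0 -> 0 convention so a constant classifier on
#' an imbalanced set scores 0 (its accuracy equals the majority-class
#' fraction).
#'
#' @name metrics
NULL

#' Build confusion counts from truth and prediction
#'
#' @param truth,pred Character or factor vectors with values
#'   `"methylated"` / `"unmethylated"`.
#' @return A `ConfusionCounts` list (`tp`, `fp`, `tn`, `fn`).
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  t_pos <- truth == "methylated"
  p_pos <- pred == "methylated"
  structure(list(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                 tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos)),
            class = "ConfusionCounts")
}

#' @rdname confusion_counts
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @export
confusion <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "ConfusionCounts")
}

#' Accuracy from confusion counts
#' @param cc A `ConfusionCounts`.
#' @return `(TP + TN) / total`.
#' @export
accuracy <- function(cc) {
  with(cc, (tp + tn) / (tp + fp + tn + fn))
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; 0 when any
#' factor of the denominator is 0 (constant classifier convention).
#'
#' @param cc A `ConfusionCounts`.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cc) {
  d <- with(cc, prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (d == 0) return(0)
  with(cc, (tp * tn - fp * fn) / sqrt(d))
}

#' Area under the ROC curve from decision scores
#'
#' Rank statistic (Mann-Whitney form): ties contribute 1/2 via midranks.
#'
#' @param scores Numeric decision scores (larger = more methylated).
#' @param labels `"methylated"` / `"unmethylated"` per score.
#' @return AUC in \[0, 1\]; errors when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "methylated"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average absolute error (regression-mode score)
#'
#' @param actual,predicted Numeric vectors of equal length in \[0, 1\].
#' @return Mean of `|actual - predicted|`.
#' @export
aae <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  mean(abs(actual - predicted))
}
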