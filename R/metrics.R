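#' Binary classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric whose denominator is zero is defined as 0 (degenerate folds).
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Named numeric vector `(sn, sp, acc, mcc)`.
#' @export
#' @examples
#' compute_metrics(tp = 45, fp = 10, tn = 40, fn = 5)
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / total
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- safe_div(tp * tn - fp * fn, denom)
  c(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted one half.
#'
#' @param scores Numeric scores (higher = more likely interacting).
#' @param labels Binary labels (1 positive / 0 negative); both classes must
#'   be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute AUC")
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, suitable for
#'   writing as TSV and plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  data.frame(threshold = r$thresholds,
             fpr = 1 - r$specificities,
             tpr = r$sensitivities)
}
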