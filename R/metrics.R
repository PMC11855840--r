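# The seven classification metrics: confusion counts at a decision
# threshold plus threshold-free ROC and precision-recall areas.

#' Compute the seven-metric classification report
#'
#' Confusion counts are taken at `threshold` on the scores; ACC, SE
#' (sensitivity), SP (specificity), MCC and F1 follow the standard
#' confusion-matrix formulas. AUC is the trapezoidal area under the ROC
#' curve and PRC the trapezoidal area under the precision-recall curve, both
#' swept over all distinct score thresholds. An MCC with a zero denominator
#' is reported as 0 with `mcc_undefined = TRUE`; with single-class labels
#' AUC and PRC are `NA`.
#'
#' @param labels 0/1 vector
#' @param scores numeric vector in [0, 1]
#' @param threshold decision threshold on the scores (default 0.5)
#' @return object of class `metrics_report`: list with counts `TP`, `FP`,
#'   `TN`, `FN` and metrics `ACC`, `SE`, `SP`, `MCC`, `F1`, `PRC`, `AUC`
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)

  acc <- (tp + tn) / length(labels)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_undef <- mcc_den == 0
  mcc <- if (mcc_undef) 0 else (tp * tn - fp * fn) / mcc_den

  both <- length(unique(labels)) == 2L
  auc <- if (both) .roc_auc(labels, scores) else NA_real_
  prc <- if (both) .pr_auc(labels, scores) else NA_real_

  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 ACC = acc, SE = se, SP = sp, MCC = mcc, F1 = f1,
                 PRC = prc, AUC = auc,
                 mcc_undefined = mcc_undef, threshold = threshold),
            class = "metrics_report")
}

# ROC/PR operating points over all distinct thresholds (descending score),
# vectorized via cumulative sums over the score-sorted labels.
.roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # keep one point per threshold
  P <- sum(lab); N <- length(lab) - P
  list(tp = c(0, tp[last]), fp = c(0, fp[last]), P = P, N = N)
}

.roc_auc <- function(labels, scores) {
  r <- .roc_points(labels, scores)
  tpr <- r$tp / r$P; fpr <- r$fp / r$N
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

.pr_auc <- function(labels, scores) {
  r <- .roc_points(labels, scores)
  tp <- r$tp[-1]; fp <- r$fp[-1]          # drop the empty point
  rec <- tp / r$P
  prec <- tp / (tp + fp)
  rec <- c(0, rec); prec <- c(prec[1], prec)  # anchor at recall 0
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP %d FP %d TN %d FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("ACC %.4f  SE %.4f  SP %.4f  MCC %.4f  F1 %.4f  PRC %.4f  AUC %.4f\n",
              x$ACC, x$SE, x$SP, x$MCC, x$F1, x$PRC, x$AUC))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(TP = x$TP, FP = x$FP, TN = x$TN, FN = x$FN, ACC = x$ACC,
             SE = x$SE, SP = x$SP, MCC = x$MCC, F1 = x$F1, PRC = x$PRC,
             AUC = x$AUC)
}
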