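# Brute-force ROC/PR areas: explicit loop over every distinct threshold.
# Independent oracle for the vectorized implementations in the package.

brute_roc_pr <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- 0; fpr <- 0; rec <- numeric(0); prec <- numeric(0)
  for (t in th) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    tpr <- c(tpr, tp / P); fpr <- c(fpr, fp / N)
    rec <- c(rec, tp / P); prec <- c(prec, tp / (tp + fp))
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  rec <- c(0, rec); prec <- c(prec[1], prec)
  prc <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  list(auc = auc, prc = prc)
}
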