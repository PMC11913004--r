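#' Binary classification metrics report
#'
#' Confusion counts at a score threshold plus accuracy, sensitivity
#' (true-positive rate among cases), specificity (true-negative rate among
#' controls) and AUC. The AUC is the Mann-Whitney rank statistic: the
#' probability that a random case outscores a random control, ties counted
#' one half. Internal identities (`tp + fp + tn + fn == n`,
#' `accuracy == (tp + tn) / n`, ...) are recomputed and asserted on every
#' construction.
#'
#' @param scores numeric vector of case-class scores (e.g. softmax
#'   probability of class 1).
#' @param labels 0/1 vector, same length.
#' @param threshold decision threshold on the score (default 0.5).
#' @return object of class `metrics_report`: fields `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `n`. `auc` is `NA`
#'   when only one class is present; `sensitivity`/`specificity` are `NA`
#'   when their denominator is zero.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stopf("scores and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  auc <- if (n1 == 0 || n0 == 0) {
    NA_real_
  } else {
    r <- rank(scores)                     # average ranks = half-credit ties
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  rep <- structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / n,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         auc = auc, n = n),
    class = "metrics_report"
  )
  stopifnot(rep$tp + rep$fp + rep$tn + rep$fn == rep$n,
            isTRUE(all.equal(rep$accuracy, (rep$tp + rep$tn) / rep$n)))
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics (n = %d): accuracy %.4f, sensitivity %s, specificity %s, AUC %s\n",
    x$n, x$accuracy,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity)),
    ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))
  ))
  cat(sprintf("  confusion: tp %d, fp %d, tn %d, fn %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
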