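## Classification metrics: one-vs-rest confusion counts, the standard
## derived ratios, macro/weighted averaging, and per-class ROC AUC.

#' Metrics from binary confusion counts
#'
#' accuracy = (TP+TN)/(TP+FP+TN+FN); sensitivity (recall) = TP/(TP+FN);
#' specificity = TN/(TN+FP); precision = TP/(TP+FP); F1 = 2PR/(P+R).
#' Undefined ratios (zero denominators) are returned as `NA`.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named numeric vector.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  p <- div(tp, tp + fp)
  r <- div(tp, tp + fn)
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) {
    if (!is.na(r) && r == 0) 0 else NA_real_
  } else 2 * p * r / (p + r)
  c(accuracy = div(tp + tn, tp + fp + tn + fn),
    sensitivity = r, specificity = div(tn, tn + fp),
    precision = p, f1 = f1)
}

# AUC of `scores` for a 0/1 response, by the rank (Mann-Whitney) statistic;
# equals the trapezoidal ROC area and gives 0.5 for constant scores.
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predictions on a test set
#'
#' Hard labels are the row-wise argmax of the probability matrix (ties to
#' the lower class index). Sensitivity, specificity, precision and F1 are
#' computed per class one-vs-rest, then macro-averaged (unweighted) and,
#' for F1, also weighted by class frequency in the test set. AUC is
#' one-vs-rest per class from the probability columns (cross-checked
#' against [pROC::roc()] in the test suite), macro-averaged. A class
#' absent from the test set is excluded from the macro averages with a
#' warning.
#'
#' @param probs n x c probability matrix over all samples.
#' @param labels Integer labels 1..c for all samples.
#' @param test_idx Indices of the evaluated samples.
#' @return A `metrics_report` list: overall `accuracy`, macro
#'   `sensitivity`/`specificity`/`precision`, `f1_macro`, `f1_weighted`,
#'   `auc_macro`, and the `per_class` table.
#' @export
evaluate <- function(probs, labels, test_idx = seq_along(labels)) {
  k <- ncol(probs)
  pred <- max.col(probs[test_idx, , drop = FALSE], ties.method = "first")
  truth <- labels[test_idx]
  n <- length(truth)
  per_class <- lapply(seq_len(k), function(c) {
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- sum(pred != c & truth == c)
    tn <- n - tp - fp - fn
    met <- confusion_metrics(tp, fp, tn, fn)
    auc <- rank_auc(probs[test_idx, c], truth == c)
    c(class = c, n_true = tp + fn, tp = tp, fp = fp, tn = tn, fn = fn,
      met, auc = auc)
  })
  per_class <- as.data.frame(do.call(rbind, per_class))
  absent <- per_class$n_true == 0
  if (any(absent)) {
    warning("class(es) absent from test set excluded from macro averages: ",
            paste(per_class$class[absent], collapse = ", "))
  }
  pc <- per_class[!absent, , drop = FALSE]
  wts <- pc$n_true / sum(pc$n_true)
  macro <- function(col) mean(pc[[col]], na.rm = TRUE)
  structure(list(
    accuracy = mean(pred == truth),
    sensitivity = macro("sensitivity"),
    specificity = macro("specificity"),
    precision = macro("precision"),
    f1_macro = macro("f1"),
    f1_weighted = sum(wts * ifelse(is.na(pc$f1), 0, pc$f1)),
    auc_macro = macro("auc"),
    per_class = per_class,
    n_evaluated = n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report: n=%d  acc=%.3f  f1_macro=%.3f  ",
                     "f1_weighted=%.3f  auc_macro=%.3f>\n"),
              x$n_evaluated, x$accuracy, x$f1_macro, x$f1_weighted,
              x$auc_macro))
  invisible(x)
}
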