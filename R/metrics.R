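#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A named list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = unname(tp), tn = unname(tn), fp = unname(fp),
              fn = unname(fn))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

## Tabulate predicted vs true labels ("positive"/"negative").
tabulate_confusion <- function(truth, predicted) {
  confusion_counts(sum(truth == "positive" & predicted == "positive"),
                   sum(truth == "negative" & predicted == "negative"),
                   sum(truth == "negative" & predicted == "positive"),
                   sum(truth == "positive" & predicted == "negative"))
}

#' Threshold-dependent classification metrics
#'
#' Sensitivity `Sn = 100 * TP/(TP+FN)`, specificity `Sp = 100 * TN/(TN+FP)`,
#' accuracy `Acc = 100 * (TP+TN)/total` and the Matthews correlation
#' coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`,
#' with `MCC = 0` when its denominator vanishes (the conventional guard for
#' the otherwise undefined case).
#'
#' @param counts A [confusion_counts] object (or a list with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return A named list of class `classification_metrics` with elements
#'   `sn`, `sp`, `acc` (percentages) and `mcc`, plus the input `counts`.
#' @examples
#' compute_metrics(confusion_counts(74, 84, 23, 33))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated peptides (total count is 0)",
                       call. = FALSE)
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / total
  denom <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 counts = confusion_counts(tp, tn, fp, fn)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("Sn %.*f%%  Sp %.*f%%  Acc %.*f%%  MCC %.2f\n", digits, x$sn,
              digits, x$sp, digits, x$acc, x$mcc))
  invisible(x)
}

## One row per metrics object, for tables mirroring the usual layout.
metrics_row <- function(m) {
  data.frame(sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc,
             tp = m$counts$tp, tn = m$counts$tn, fp = m$counts$fp,
             fn = m$counts$fn)
}
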