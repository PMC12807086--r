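#' Confusion counts for binary methylation calls
#'
#' Positives are methylated examples (label 1). `P = TP + FN` and
#' `N = FP + TN` partition the examples.
#'
#' @param labels Integer 0/1 truth labels.
#' @param calls Integer 0/1 predicted calls, same length.
#' @return A list of class `meth_confusion` with `TP`, `FP`, `FN`, `TN`,
#'   `P`, `N`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop("labels and calls must have the same length")
  }
  if (!all(labels %in% c(0L, 1L)) || !all(calls %in% c(0L, 1L))) {
    stop("labels and calls must be 0/1")
  }
  tp <- sum(labels == 1L & calls == 1L)
  fp <- sum(labels == 0L & calls == 1L)
  fn <- sum(labels == 1L & calls == 0L)
  tn <- sum(labels == 0L & calls == 0L)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn, P = tp + fn, N = fp + tn),
            class = "meth_confusion")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / (P + N)`, precision `TP / (TP + FP)`, recall
#' `TP / P`, and F1, the harmonic mean of precision and recall. A ratio with
#' a zero denominator is reported as 0 and its name recorded in the
#' `undefined` field, keeping reports machine-readable.
#'
#' @param conf A `meth_confusion` from [confusion()].
#' @return A list of class `meth_metrics`: `accuracy`, `precision`,
#'   `recall`, `f1`, `undefined` (character vector).
#' @export
metrics_report <- function(conf) {
  stopifnot(inherits(conf, "meth_confusion"))
  total <- conf$P + conf$N
  if (total < 1L) stop("metrics require at least one example")
  undef <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      return(0)
    }
    num / den
  }
  acc <- (conf$TP + conf$TN) / total
  prec <- safe(conf$TP, conf$TP + conf$FP, "precision")
  rec <- safe(conf$TP, conf$P, "recall")
  f1 <- safe(2 * prec * rec, prec + rec, "f1")
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 undefined = undef),
            class = "meth_metrics")
}

#' @export
print.meth_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f%s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              if (length(x$undefined)) {
                paste0(" (undefined: ", paste(x$undefined, collapse = ", "), ")")
              } else ""))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney pairwise-concordance formulation computed from ranks; tied
#' scores count 0.5.
#'
#' @param labels Integer 0/1 truth labels (both classes required).
#' @param probs Numeric scores (higher = more likely methylated).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, probs) {
  if (length(labels) != length(probs)) {
    stop("labels and probs must have the same length")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions against labels
#'
#' Joins per-read predictions with truth labels on
#' (read_id, chrom, strand, ref_pos) and computes the full metric report
#' plus AUC.
#'
#' @param predictions Data frame from [predict_windows()] or
#'   [read_predictions()].
#' @param labels Data frame from [read_labels()].
#' @return List with `confusion`, `metrics`, `auc`, `n`.
#' @export
evaluate_predictions <- function(predictions, labels) {
  pk <- paste(predictions$read_id, predictions$chrom, predictions$strand,
              predictions$ref_pos)
  lk <- paste(labels$read_id, labels$chrom, labels$strand, labels$ref_pos)
  m <- match(pk, lk)
  keep <- !is.na(m)
  if (!any(keep)) stop("no predictions match the label set")
  y <- labels$label[m[keep]]
  conf <- confusion(y, predictions$call[keep])
  auc <- if (length(unique(y)) == 2L) roc_auc(y, predictions$prob[keep]) else NA_real_
  list(confusion = conf, metrics = metrics_report(conf), auc = auc,
       n = sum(keep))
}
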