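# Confusion-matrix classification metrics: balanced accuracy, sensitivity,
# specificity, F-score, MCC, Cohen's kappa and Youden's index. The positive
# class is abnormal (label 1); ties at the threshold predict positive.

#' Round half away from zero
#'
#' Display rounding matching the 4-decimal report convention (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Confusion counts at a threshold
#'
#' A sample is predicted positive (abnormal) iff its abnormal-class
#' probability is `>= threshold`.
#'
#' @param p_abnormal Numeric vector of abnormal-class probabilities in
#'   \[0, 1\].
#' @param labels Binary labels (1 = abnormal).
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `confusion_counts` with tp, fp, tn, fn.
#' @export
confusion <- function(p_abnormal, labels, threshold = 0.5) {
  if (length(p_abnormal) != length(labels)) stop("length mismatch")
  if (any(p_abnormal < 0 | p_abnormal > 1)) stop("probabilities outside [0, 1]")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  pred <- as.integer(p_abnormal >= threshold)
  structure(list(tp = sum(pred == 1L & labels == 1L),
                 fp = sum(pred == 1L & labels == 0L),
                 tn = sum(pred == 0L & labels == 0L),
                 fn = sum(pred == 0L & labels == 1L),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' (their mean), F-score `2TP/(2TP+FP+FN)`, Matthews correlation
#' coefficient, Cohen's kappa and Youden's index
#' (sensitivity + specificity - 1).
#'
#' @param counts A `confusion_counts` object, or a list with tp, fp, tn, fn.
#' @return A one-row data.frame (class `metric_report`) with columns
#'   balanced_accuracy, sensitivity, specificity, f_score, mcc, kappa,
#'   youden.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0) stop("undefined metric: sensitivity (no positives)")
  if (tn + fp == 0) stop("undefined metric: specificity (no negatives)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f <- 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  pe <- (as.numeric(tp + fp) * (tp + fn) + as.numeric(tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  out <- data.frame(balanced_accuracy = (sens + spec) / 2,
                    sensitivity = sens, specificity = spec,
                    f_score = f, mcc = mcc, kappa = kappa,
                    youden = sens + spec - 1)
  class(out) <- c("metric_report", class(out))
  out
}

#' Metrics straight from probabilities
#'
#' @inheritParams confusion
#' @return A `metric_report` data.frame.
#' @export
evaluate_predictions <- function(p_abnormal, labels, threshold = 0.5) {
  compute_metrics(confusion(p_abnormal, labels, threshold))
}
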