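#' Confusion-matrix counts over trial verdicts
#'
#' Cross-tabulates the true product status against method decisions.
#' Truly-bioequivalent trials declared bioequivalent are true positives
#' (TP); declared not, false negatives (FN). Truly-bioinequivalent trials
#' declared bioequivalent are false positives (FP); declared not, true
#' negatives (TN).
#'
#' @param truth Logical (TRUE = truly bioequivalent) or character
#'   (`"bioequivalent"` counts as TRUE).
#' @param decision Logical method verdicts, same length.
#' @return One-row tibble with `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, TRUE))
confusion_counts <- function(truth, decision) {
  if (is.character(truth)) truth <- truth == "bioequivalent"
  stopifnot(is.logical(truth), is.logical(decision),
            length(truth) == length(decision))
  tibble(tp = sum(truth & decision), fn = sum(truth & !decision),
         fp = sum(!truth & decision), tn = sum(!truth & !decision))
}

#' Performance statistics of a confusion matrix
#'
#' The eight derived statistics, reported in percent: sensitivity (power,
#' 1 - type II error rate), specificity (1 - type I error rate), precision
#' (positive predictive value), negative predictive value, accuracy, the F1
#' score (harmonic mean of sensitivity and precision), the Matthews
#' correlation coefficient, and the two-class Cohen's kappa
#' `2 (tp tn - fp fn) / ((tp+fp)(fp+tn) + (tp+fn)(fn+tn))`.
#'
#' A statistic whose denominator is zero is reported as `NA` (undefined,
#' never silently zero) and the `degenerate` flag is set.
#'
#' @param tp,fn,fp,tn Confusion counts, or pass a one-row tibble from
#'   [confusion_counts()] as `tp`.
#' @return One-row tibble: counts, the eight statistics (percent) and
#'   `degenerate`.
#' @export
#' @examples
#' confusion_stats(tp = 79, fn = 21, fp = 0, tn = 100)
confusion_stats <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.data.frame(tp)) {
    fn <- tp$fn; fp <- tp$fp; tn <- tp$tn; tp <- tp$tp
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  prec <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  acc <- rate(tp + tn, tp + fn + fp + tn)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  kap_den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  kappa <- if (kap_den > 0) 2 * (tp * tn - fp * fn) / kap_den else NA_real_
  out <- tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = 100 * sens, specificity = 100 * spec,
    precision = 100 * prec, npv = 100 * npv, accuracy = 100 * acc,
    f1 = 100 * f1, mcc = 100 * mcc, kappa = 100 * kappa
  )
  out$degenerate <- anyNA(out)
  out
}
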