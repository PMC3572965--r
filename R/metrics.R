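# 2x2 classification metrics for the at-risk pattern.

#' Classification metrics from a 2x2 confusion table
#'
#' Standard definitions, reported as percentages: sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive value
#' `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`. A metric whose
#' denominator is zero is reported as `NA` (absent), never as 0. Counts
#' need not be integers, so tables reconstructed from printed rates (see
#' [reconstruct_confusion()]) can be scored.
#'
#' @param tp,fn,fp,tn confusion-table cells (events predicted at risk,
#'   events missed, non-events predicted at risk, non-events cleared).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` (percent)
#'   and the cell counts.
#' @export
metrics_from_confusion <- function(tp, fn, fp, tn) {
  stopifnot(all(c(tp, fn, fp, tn) >= 0))
  if (tp + fn == 0 || tn + fp == 0) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp),
       npv = pct(tn, tn + fn),
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Classification metrics of the at-risk prediction
#'
#' Cross-tabulates a binary at-risk prediction (conventionally
#' `pattern == "pattern3"`) against the incident MCI/dementia labels and
#' returns the four standard metrics.
#'
#' @param predicted_at_risk logical vector, `TRUE` for subjects predicted
#'   at risk.
#' @param labels per-subject outcome labels (logical, or anything
#'   accepted by the tree-building functions).
#' @return See [metrics_from_confusion()].
#' @export
classification_metrics <- function(predicted_at_risk, labels) {
  y <- .as_event(labels)
  p <- as.logical(predicted_at_risk)
  stopifnot(length(p) == length(y), !anyNA(p), !anyNA(y))
  metrics_from_confusion(tp = sum(p & y), fn = sum(!p & y),
                         fp = sum(p & !y), tn = sum(!p & !y))
}

#' Reconstruct a 2x2 table from printed sensitivity/specificity
#'
#' Given sensitivity and specificity (as proportions in `[0, 1]`) and the
#' event / non-event margins, recovers the implied confusion-table cells
#' (`TP = sens * n_event`, etc.). Cells are generally non-integer when
#' the rates were printed rounded; [metrics_from_confusion()] accepts
#' them as is, which is how predictive values are re-derived from a
#' report that prints only sensitivity, specificity and the margins.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @param n_event,n_nonevent the two margins.
#' @return List with `tp`, `fn`, `fp`, `tn`.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_event,
                                  n_nonevent) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_event > 0, n_nonevent > 0)
  list(tp = sensitivity * n_event,
       fn = (1 - sensitivity) * n_event,
       tn = specificity * n_nonevent,
       fp = (1 - specificity) * n_nonevent)
}
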