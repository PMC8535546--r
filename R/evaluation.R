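#' True adherence label of a user
#'
#' A user is non-adherent when they show no training activity over the
#' entire fourth month (days 91-120 all zero); any positive activity makes
#' them adherent.
#'
#' @param series a 120-day `daily_series` (or plain 120-vector).
#' @return `"adherent"` or `"non_adherent"`.
#' @export
true_label <- function(series) {
  w <- split_windows(series)
  if (all(w$test == 0)) "non_adherent" else "adherent"
}

#' Predicted adherence label from a month-4 forecast
#'
#' Regression forecasts are rarely exactly zero, so the all-zero rule is
#' applied through a small activity threshold: the user is predicted
#' adherent when the forecast's total predicted workout time reaches `tau`
#' seconds over the month.
#'
#' @param pred_month4 30 non-negative forecast values (seconds/day).
#' @param tau adherence threshold in predicted seconds per month.
#'   Default 60 s — effectively "any predicted activity", and small against
#'   typical monthly activity totals.
#' @return `"adherent"` or `"non_adherent"`.
#' @export
predicted_label <- function(pred_month4, tau = 60) {
  p <- as.numeric(pred_month4)
  if (length(p) != 30L)
    stop("expected a 30-day forecast, got length ", length(p), call. = FALSE)
  if (any(p < 0)) stop("negative forecast values", call. = FALSE)
  if (sum(p) >= tau) "adherent" else "non_adherent"
}

#' Confusion matrix for adherence classification
#'
#' The positive class is `adherent` (the user exercised in month 4):
#' TP/TN count correct adherent/non-adherent predictions, FP users
#' predicted to exercise who did not, FN users predicted to stop who in
#' fact exercised.
#'
#' @param truth,predicted equal-length vectors of
#'   `"adherent"`/`"non_adherent"` labels.
#' @return A `confusion_matrix` with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  pos <- "adherent"
  confusion_matrix(
    tp = sum(truth == pos & predicted == pos),
    tn = sum(truth != pos & predicted != pos),
    fp = sum(truth != pos & predicted == pos),
    fn = sum(truth == pos & predicted != pos)
  )
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative integer counts.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, byrow = TRUE,
              dimnames = list(c("Actual: No", "Actual: Yes"),
                              c("Predicted: No", "Predicted: Yes")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and F1 (harmonic mean of precision and
#' recall). A zero denominator yields `NA` for that metric rather than an
#' error.
#'
#' @param cm a `confusion_matrix`.
#' @return Named list with `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`.
#' @export
metrics <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  precision <- safe_div(cm$tp, cm$tp + cm$fp)
  recall <- safe_div(cm$tp, cm$tp + cm$fn)
  list(
    accuracy = (cm$tp + cm$tn) / n,
    precision = precision,
    recall = recall,
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    f1 = f1_score(precision, recall)
  )
}

#' F1 score from precision and recall
#'
#' @param precision,recall proportions in `[0, 1]` (possibly `NA`).
#' @return `2 * precision * recall / (precision + recall)`, or `NA` when
#'   undefined.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}
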