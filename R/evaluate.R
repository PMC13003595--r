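# Classification metrics.
#
# Accuracy, F1 and ROC/AUC are computed by one shared code path for the
# network and every baseline. AUC uses the Mann-Whitney convention (ties
# credited 1/2), which makes trapezoidal integration of the empirical ROC and
# concordant-pair counting identical.

check_binary <- function(v, what) {
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop_invalid("%s must be a 0/1 vector", what)
  as.numeric(v)
}

#' Classification accuracy
#'
#' @param labels,predictions Equal-length 0/1 vectors.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop_invalid("length mismatch")
  labels <- check_binary(labels, "labels")
  predictions <- check_binary(predictions, "predictions")
  mean(labels == predictions)
}

#' F1 score of the positive class
#'
#' Harmonic mean of precision and recall. When there are no predicted and no
#' actual positives the score is defined as 0 with a warning.
#'
#' @param labels,predictions Equal-length 0/1 vectors.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop_invalid("length mismatch")
  labels <- check_binary(labels, "labels")
  predictions <- check_binary(predictions, "predictions")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  if (2 * tp + fp + fn == 0) {
    warn("no positives in labels or predictions; F1 defined as 0")
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score threshold to build the empirical ROC and
#' integrates it by the trapezoidal rule. With ties credited 1/2 this equals
#' the Mann-Whitney pair statistic: the probability a random positive
#' outscores a random negative.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Real-valued scores, higher = more positive.
#' @return List with `roc` (tibble of `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop_invalid("length mismatch")
  labels <- check_binary(labels, "labels")
  if (length(unique(labels)) < 2) stop_invalid("both classes must be present for ROC")
  if (anyNA(scores)) stop_invalid("scores must not contain NA")

  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, numeric(1))
  roc <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (utils::tail(roc$fpr, 1) != 1 || utils::tail(roc$tpr, 1) != 1)
    roc <- dplyr::bind_rows(roc, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = structure(roc, class = c("hibpn_roc", class(roc))), auc = auc)
}

#' Relative performance gap between two metric values
#'
#' `100 * (reference - value) / denominator`, where the denominator is either
#' the reference (full/leading model, the default) or the compared value
#' (ablated model). Both conventions appear in reported drop percentages, so
#' both are exposed.
#'
#' @param reference Metric of the reference (full) model.
#' @param value Metric of the compared model.
#' @param denominator_mode `"reference"` (default) or `"value"`.
#' @return Gap in percent (positive when the reference is larger).
#' @examples
#' relative_gap(0.884, 0.630) # 28.73: decision tree vs full model AUC
#' relative_gap(0.694, 0.514, "value") # 35.02: ablation ACC drop
#' @export
relative_gap <- function(reference, value,
                         denominator_mode = c("reference", "value")) {
  denominator_mode <- match.arg(denominator_mode)
  den <- if (denominator_mode == "reference") reference else value
  if (den == 0) stop_invalid("zero denominator in relative gap")
  100 * (reference - value) / den
}

#' Minimum margin over ACC/AUC/F1 against the best baseline
#'
#' For each metric, computes the gap between the leading model and the best
#' baseline as a percentage of the leading model's value, and returns the
#' smallest of the three gaps.
#'
#' @param lead_metrics Named numeric with `acc`, `auc`, `f1` for the leading
#'   model.
#' @param baseline_table Data frame with columns `acc`, `auc`, `f1`, one row
#'   per baseline.
#' @return Minimum gap in percent.
#' @export
min_margin_across_metrics <- function(lead_metrics, baseline_table) {
  needed <- c("acc", "auc", "f1")
  if (!all(needed %in% names(lead_metrics)) || !all(needed %in% names(baseline_table)))
    stop_invalid("metrics table must contain acc, auc and f1")
  gaps <- vapply(needed, function(m) {
    relative_gap(lead_metrics[[m]], max(baseline_table[[m]]), "reference")
  }, numeric(1))
  min(gaps)
}

#' Evaluate predicted scores against labels
#'
#' One call computing the full metric row used throughout the comparison and
#' ablation tables.
#'
#' @param labels 0/1 vector.
#' @param scores Real-valued scores (probability of the positive class where
#'   available).
#' @param threshold Classification threshold on the scores (default 0.5).
#' @return Tibble row: `acc`, `f1`, `auc`, `n_test`, plus `roc` as a nested
#'   list-column.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  preds <- as.integer(scores >= threshold)
  ra <- roc_and_auc(labels, scores)
  tibble::tibble(acc = accuracy(labels, preds), f1 = f1_score(labels, preds),
                 auc = ra$auc, n_test = length(labels), roc = list(ra$roc))
}
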