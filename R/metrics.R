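## Window-level classification metrics and the rank-based AUC.

#' Area under the ROC curve (rank statistic with tie midranks)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, counting ties as one half.
#'
#' @param scores numeric scores (higher = more seizure-like).
#' @param labels 0/1 labels containing both classes.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_eegdann("AUC undefined: labels contain a single class",
                 "eegdann_auc_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts and threshold metrics for scored windows
#'
#' Accuracy, sensitivity (true-positive rate), specificity (true-negative
#' rate), F1 and threshold-free AUC. A window is called positive when its
#' score is at least `threshold`.
#'
#' @param scores numeric scores/probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with `counts` (tp, tn, fp, fn) and `metrics` (accuracy,
#'   sensitivity, specificity, f1, auc; AUC is NA with a warning when only
#'   one class is present).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) >= 1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  auc <- tryCatch(auc_score(scores, labels), eegdann_auc_error = function(e) {
    warning(conditionMessage(e))
    NA_real_
  })
  list(
    counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
    metrics = list(
      accuracy = (tp + tn) / length(labels),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
      auc = auc
    )
  )
}

#' Aggregate per-fold metric lists into a mean +/- sd report
#'
#' @param per_fold list of `metrics` lists (one per fold).
#' @return a `metrics_report`: list with `per_fold` (data.frame), `mean`,
#'   `sd`.
#' @export
metrics_report <- function(per_fold) {
  df <- do.call(rbind, lapply(per_fold, function(m) as.data.frame(m)))
  rownames(df) <- NULL
  structure(
    list(per_fold = df,
         mean = colMeans(df, na.rm = TRUE),
         sd = apply(df, 2, sd, na.rm = TRUE)),
    class = "metrics_report"
  )
}
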