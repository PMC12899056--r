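## Z-score normalization of spectrogram batches.
##
## One global (mean, sd) pair over all training spectrogram bins; the fitted
## statistics object records the subject ids it was computed from so that
## train/eval leakage can be detected when the statistics are applied.

#' Fit global z-score statistics on a training spectrogram batch
#'
#' @param s a `spectrogram_batch` with `split_role == "train"`.
#' @return a `zscore_stats`: list with `mean`, `sd`, `fitted_subjects`.
#' @export
fit_zscore_stats <- function(s) {
  stopifnot(inherits(s, "spectrogram_batch"))
  if (s$split_role != "train") {
    stop_eegdann("normalization statistics must be fitted on training data",
                 "eegdann_leakage_error")
  }
  m <- mean(s$tensor)
  sdev <- sd(as.vector(s$tensor))
  if (!is.finite(sdev) || sdev < 1e-12) {
    stop_eegdann("degenerate (zero-variance) spectrogram batch",
                 "eegdann_degenerate_error")
  }
  structure(
    list(mean = m, sd = sdev, fitted_subjects = unique(s$subject_ids)),
    class = "zscore_stats"
  )
}

#' Apply fitted z-score statistics to a spectrogram batch
#'
#' Evaluation batches are normalized with the training statistics. Applying
#' train-fitted statistics to an evaluation batch that shares subjects with
#' the fit is a leakage error (disable with `check_leakage = FALSE` when the
#' overlap is intentional, e.g. normalizing the training batch itself).
#'
#' @param s a `spectrogram_batch`.
#' @param stats a `zscore_stats` from [fit_zscore_stats()].
#' @param check_leakage check subject overlap for eval batches.
#' @return the batch with normalized tensor and `normalized = TRUE`.
#' @export
apply_zscore <- function(s, stats, check_leakage = TRUE) {
  stopifnot(inherits(s, "spectrogram_batch"), inherits(stats, "zscore_stats"))
  if (check_leakage && s$split_role == "eval") {
    overlap <- intersect(unique(s$subject_ids), stats$fitted_subjects)
    if (length(overlap) > 0) {
      stop_eegdann(
        sprintf("normalization statistics were fitted on evaluation subject(s): %s",
                paste(overlap, collapse = ", ")),
        "eegdann_leakage_error"
      )
    }
  }
  s$tensor <- (s$tensor - stats$mean) / stats$sd
  s$normalized <- TRUE
  s$norm_stats <- stats
  s
}

#' Fit-and-apply z-score normalization on a training batch
#'
#' @param s a training-role `spectrogram_batch`.
#' @return the normalized batch, with the fitted statistics in `$norm_stats`.
#' @export
zscore_normalize <- function(s) {
  stats <- fit_zscore_stats(s)
  apply_zscore(s, stats, check_leakage = FALSE)
}
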