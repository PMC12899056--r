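## Sliding-window segmentation with center-point consensus labeling.

#' Segment a 128 Hz bipolar recording into labeled 2-s windows
#'
#' Training-role windows start every 1 s (50% overlap, a data augmentation
#' used only for training); evaluation-role windows start every 2 s (no
#' overlap). Each window's label is the consensus at its central second: for
#' the window covering `[t0, t0 + 2)` seconds this is second index `t0 + 1`
#' (0-based). Windows extending past the signal or annotation end are
#' dropped.
#'
#' @param x a `bipolar_recording` at 128 Hz.
#' @param consensus a `consensus_track` from [consensus_per_second()].
#' @param role `"train"` or `"eval"`.
#' @param subject_id subject identifier attached to every window.
#' @return a `window_set`: list with `windows` (N x 18 x 256 array), `labels`
#'   (N 0/1), `subject_ids`, `start_times_s`, `split_role`.
#' @export
segment_windows <- function(x, consensus, role = c("train", "eval"),
                            subject_id = consensus$subject_id %||% "unknown") {
  role <- match.arg(role)
  stopifnot(inherits(x, "bipolar_recording"))
  if (x$fs != 128) {
    stop_eegdann("segment_windows expects a 128 Hz recording",
                 "eegdann_rate_error")
  }
  n_ch <- nrow(x$signal)
  dur_s <- floor(ncol(x$signal) / x$fs)
  t_ann <- length(consensus$consensus)
  usable_s <- min(dur_s, t_ann)
  step <- if (role == "train") 1L else 2L
  starts <- seq(0L, by = step, length.out = max(0, floor((usable_s - 2) / step) + 1))
  if (usable_s < 2 || length(starts) == 0) {
    warning("recording shorter than one 2-s window; empty window set")
    return(structure(
      list(windows = array(0, dim = c(0, n_ch, 256)), labels = integer(0),
           subject_ids = character(0), start_times_s = numeric(0),
           split_role = role),
      class = "window_set"
    ))
  }
  n <- length(starts)
  win <- array(0, dim = c(n, n_ch, 256))
  for (i in seq_len(n)) {
    i0 <- starts[i] * x$fs
    win[i, , ] <- x$signal[, (i0 + 1):(i0 + 256)]
  }
  labels <- consensus$consensus[starts + 2L] # central second t0 + 1, 0-based
  structure(
    list(windows = win, labels = as.integer(labels),
         subject_ids = rep(subject_id, n), start_times_s = as.numeric(starts),
         split_role = role),
    class = "window_set"
  )
}

#' Concatenate window sets (e.g. across subjects)
#'
#' All inputs must share the split role.
#' @param ... `window_set` objects (or a single list of them).
#' @return a combined `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  sets <- Filter(function(s) dim(s$windows)[1] > 0, sets)
  stopifnot(length(sets) > 0)
  roles <- unique(vapply(sets, function(s) s$split_role, ""))
  if (length(roles) != 1) {
    stop_eegdann("cannot bind window sets with mixed split roles",
                 "eegdann_validation_error")
  }
  n_tot <- sum(vapply(sets, function(s) dim(s$windows)[1], 0L))
  n_ch <- dim(sets[[1]]$windows)[2]
  win <- array(0, dim = c(n_tot, n_ch, 256))
  at <- 1L
  for (s in sets) {
    k <- dim(s$windows)[1]
    win[at:(at + k - 1), , ] <- s$windows
    at <- at + k
  }
  structure(
    list(windows = win,
         labels = unlist(lapply(sets, `[[`, "labels"), use.names = FALSE),
         subject_ids = unlist(lapply(sets, `[[`, "subject_ids"),
                              use.names = FALSE),
         start_times_s = unlist(lapply(sets, `[[`, "start_times_s"),
                                use.names = FALSE),
         split_role = roles),
    class = "window_set"
  )
}

#' Subset a window set by index
#' @param w a `window_set`.
#' @param idx integer indices of windows to keep.
#' @return a `window_set` with the selected windows.
#' @export
subset_window_set <- function(w, idx) {
  structure(
    list(windows = w$windows[idx, , , drop = FALSE],
         labels = w$labels[idx],
         subject_ids = w$subject_ids[idx],
         start_times_s = w$start_times_s[idx],
         split_role = w$split_role),
    class = "window_set"
  )
}

#' Full preprocessing of one recording: montage, decimation, segmentation
#'
#' Convenience wrapper chaining [derive_bipolar_montage()],
#' [downsample_signal()], [consensus_per_second()] and [segment_windows()].
#'
#' @param rec an `eeg_recording` at 256 Hz.
#' @param role `"train"` or `"eval"`.
#' @return a `window_set`.
#' @export
preprocess_recording <- function(rec, role = c("train", "eval")) {
  role <- match.arg(role)
  bp <- downsample_signal(derive_bipolar_montage(rec))
  ct <- consensus_per_second(rec)
  segment_windows(bp, ct, role, subject_id = rec$subject_id)
}

#' Preprocess a whole cohort into one window set
#' @param cohort list of `eeg_recording`s.
#' @param role `"train"` or `"eval"`.
#' @return a combined `window_set`.
#' @export
preprocess_cohort <- function(cohort, role = c("train", "eval")) {
  role <- match.arg(role)
  bind_window_sets(lapply(cohort, preprocess_recording, role = role))
}
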