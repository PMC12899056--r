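## 10-20 electrode set and the fixed 18-channel longitudinal bipolar montage.

#' The 19 standard 10-20 electrode labels used by the pipeline
#' @export
ELECTRODES_1020 <- c(
  "Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
  "C3", "C4", "Cz", "P3", "P4", "Pz",
  "T3", "T4", "T5", "T6", "O1", "O2"
)

#' The fixed ordered list of 18 bipolar channel pairs
#'
#' The "double banana" longitudinal arrangement. Channel order is a contract:
#' the spatial Bi-LSTM scans channels in exactly this sequence.
#'
#' @return a 18 x 2 character matrix (first electrode, second electrode).
#' @export
bipolar_pairs <- function() {
  p <- c(
    "Fp2", "F4", "F4", "C4", "C4", "P4", "P4", "O2",
    "Fp1", "F3", "F3", "C3", "C3", "P3", "P3", "O1",
    "Fp2", "F8", "F8", "T4", "T4", "T6", "T6", "O2",
    "Fp1", "F7", "F7", "T3", "T3", "T5", "T5", "O1",
    "Fz", "Cz", "Cz", "Pz"
  )
  matrix(p, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("first", "second")))
}

#' Bipolar channel names in the fixed montage order
#' @return character vector of length 18, e.g. `"Fp2-F4"`.
#' @export
bipolar_channel_names <- function() {
  pr <- bipolar_pairs()
  paste0(pr[, 1], "-", pr[, 2])
}

#' Derive the 18-channel bipolar montage from a 19-electrode recording
#'
#' Each bipolar channel is the potential difference `first - second` of its
#' electrode pair, in the fixed montage order.
#'
#' @param rec an [eeg_recording()] (or any list with a `signal` matrix whose
#'   rownames are 10-20 electrode labels, and `fs`).
#' @return an object of class `bipolar_recording`: list with `signal`
#'   (18 x T matrix), `fs`, `channel_names`.
#' @export
derive_bipolar_montage <- function(rec) {
  sig <- rec$signal
  if (is.null(rownames(sig))) {
    stop_eegdann("recording signal must carry electrode rownames",
                 "eegdann_montage_error")
  }
  # case-insensitive label lookup
  have <- tolower(rownames(sig))
  pr <- bipolar_pairs()
  need <- unique(c(pr))
  missing <- need[!(tolower(need) %in% have)]
  if (length(missing) > 0) {
    stop_eegdann(
      sprintf("missing electrode(s) for bipolar montage: %s",
              paste(missing, collapse = ", ")),
      "eegdann_montage_error"
    )
  }
  idx <- function(lbl) match(tolower(lbl), have)
  out <- sig[idx(pr[, 1]), , drop = FALSE] - sig[idx(pr[, 2]), , drop = FALSE]
  rownames(out) <- bipolar_channel_names()
  structure(
    list(signal = out, fs = rec$fs, channel_names = bipolar_channel_names()),
    class = "bipolar_recording"
  )
}
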