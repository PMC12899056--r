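## Minimal European Data Format (EDF) writer and reader.
##
## Supports the subset needed here: continuous 16-bit recordings, one data
## record per second, identical sampling rate on all signals. Header fields
## are plain ASCII per the EDF specification (256 bytes global + 256 bytes per
## signal); samples are little-endian two's-complement 16-bit integers scaled
## linearly between the physical and digital extrema.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write an EEG recording to an EDF file
#'
#' @param rec an `eeg_recording` (or list with `signal` channels-by-samples
#'   matrix carrying rownames, and `fs`); the duration is truncated to whole
#'   seconds.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sig <- rec$signal
  fs <- rec$fs
  if (fs != round(fs)) {
    stop_eegdann("EDF writer requires an integer sampling rate",
                 "eegdann_edf_error")
  }
  ns <- nrow(sig)
  n_rec <- floor(ncol(sig) / fs)
  sig <- sig[, seq_len(n_rec * fs), drop = FALSE]
  # per-channel symmetric physical range; avoid zero-width ranges
  pmax_ <- pmax(apply(abs(sig), 1, max), 1e-3) * 1.0001
  labels <- rownames(sig) %||% paste0("ch", seq_len(ns))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(rec$subject_id %||% "X", 80)
  wr("Startdate 01-JAN-2026 synthetic", 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(256 + 256 * ns, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (i in seq_len(ns)) wr(labels[i], 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", -pmax_[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", pmax_[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # re-read the rounded physical extrema so scaling matches the header exactly
  pmin_h <- as.numeric(sprintf("%.2f", -pmax_))
  pmax_h <- as.numeric(sprintf("%.2f", pmax_))
  scale_ <- (32767 - (-32768)) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((sig[i, cols] - pmin_h[i]) * scale_[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written with 16-bit continuous signals
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix, physical units,
#'   rownames = signal labels), `fs`, `subject_id`, `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") {
    stop_eegdann("unsupported EDF version", "eegdann_edf_error")
  }
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  stopifnot(header_bytes == 256 + 256 * ns)
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale_ <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dmin_[i]) * scale_[i] + pmin_[i]
    }
  }
  rownames(sig) <- labels
  list(signal = sig, fs = spr[1] / rec_dur, subject_id = patient,
       n_records = n_rec)
}
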