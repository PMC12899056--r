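## Signal processing: anti-aliased 2x decimation and the log-magnitude STFT.

# Linear-phase windowed-sinc low-pass FIR (Hamming window), odd length.
fir_lowpass <- function(cutoff_norm, n_taps = 65) {
  stopifnot(n_taps %% 2 == 1)
  m <- (n_taps - 1) / 2
  n <- seq(-m, m)
  h <- 2 * cutoff_norm * sinc(2 * cutoff_norm * n)
  w <- 0.54 + 0.46 * cos(pi * n / m) # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Centered FIR filtering with reflected edges (delay-compensated, so the
# output of the symmetric filter is zero-phase).
filter_centered <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  xp <- c(rev(x[2:(m + 1)]), x, rev(x[(n - m):(n - 1)]))
  y <- stats::convolve(xp, rev(h), type = "filter")
  y
}

#' Downsample a bipolar recording from 256 Hz to 128 Hz
#'
#' Applies a zero-phase anti-aliasing low-pass (windowed-sinc FIR with cutoff
#' at the new Nyquist frequency) and keeps every second sample.
#'
#' @param x a `bipolar_recording` at 256 Hz.
#' @return a `bipolar_recording` at 128 Hz with half the samples.
#' @export
downsample_signal <- function(x) {
  stopifnot(inherits(x, "bipolar_recording"))
  if (x$fs != 256) {
    stop_eegdann(sprintf("expected input at 256 Hz, got %s Hz", x$fs),
                 "eegdann_rate_error")
  }
  h <- fir_lowpass(cutoff_norm = 0.25, n_taps = 65) # 64 Hz at fs = 256
  filt <- t(apply(x$signal, 1, filter_centered, h = h))
  keep <- seq(1, ncol(filt), by = 2)
  out <- filt[, keep, drop = FALSE]
  rownames(out) <- rownames(x$signal)
  structure(
    list(signal = out, fs = 128, channel_names = x$channel_names),
    class = "bipolar_recording"
  )
}

#' STFT parameters used throughout the pipeline
#'
#' 64-point FFT, Hann analysis window of the same length, hop 16, centered
#' (reflect padding). At 128 Hz this yields 33 one-sided frequency bins with
#' 2 Hz spacing and 17 frames per 2-s (256-sample) window.
#' @return list with `n_fft`, `hop`, `fs`, `n_freq`, `n_frames`,
#'   `freq_res_hz`.
#' @export
stft_params <- function() {
  list(n_fft = 64L, hop = 16L, fs = 128, n_freq = 33L, n_frames = 17L,
       freq_res_hz = 128 / 64)
}

# Periodic Hann window (matches common STFT implementations).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# STFT magnitudes of a single 256-sample vector: 33 x 17 matrix.
stft_mag_single <- function(x, p = stft_params()) {
  half <- p$n_fft / 2
  xp <- c(rev(x[2:(half + 1)]), x, rev(x[(length(x) - half):(length(x) - 1)]))
  starts <- seq(1, length(x) + 1, by = p$hop)
  frames <- vapply(starts, function(s) xp[s:(s + p$n_fft - 1)],
                   numeric(p$n_fft))
  frames <- frames * hann_window(p$n_fft)
  spec <- stats::mvfft(frames)
  Mod(spec[seq_len(p$n_freq), , drop = FALSE])
}

#' Log-magnitude STFT spectrograms of a window set
#'
#' Per channel, a centered short-time Fourier transform with a 64-point FFT,
#' Hann analysis window and hop 16, giving 33 one-sided frequency bins (0-64
#' Hz in 2 Hz steps) by 17 frames; the output is `ln(|S| + eps)`.
#'
#' @param w a `window_set` from [segment_windows()].
#' @param eps log floor added to magnitudes before the logarithm.
#' @return a `spectrogram_batch`: list with `tensor` (N x 18 x 33 x 17
#'   array), `labels`, `subject_ids`, `start_times_s`, `split_role`,
#'   `normalized = FALSE`, `params`.
#' @export
stft_logmag <- function(w, eps = 1e-8) {
  stopifnot(inherits(w, "window_set"))
  p <- stft_params()
  n <- dim(w$windows)[1]
  n_ch <- dim(w$windows)[2]
  if (dim(w$windows)[3] != 256) {
    stop_eegdann("windows must have 256 samples per channel",
                 "eegdann_shape_error")
  }
  tensor <- array(0, dim = c(n, n_ch, p$n_freq, p$n_frames))
  for (i in seq_len(n)) {
    for (c_ in seq_len(n_ch)) {
      tensor[i, c_, , ] <- stft_mag_single(w$windows[i, c_, ], p)
    }
  }
  tensor <- log(tensor + eps)
  structure(
    list(tensor = tensor, labels = w$labels, subject_ids = w$subject_ids,
         start_times_s = w$start_times_s, split_role = w$split_role,
         normalized = FALSE, params = p),
    class = "spectrogram_batch"
  )
}
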