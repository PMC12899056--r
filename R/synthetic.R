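## Synthetic multi-subject neonatal EEG cohort generator.
##
## The generator emulates the statistical structure that matters for testing a
## cross-subject detector: per-subject 1/f^beta background with a subject-
## specific amplitude gain (domain shift), a narrowband background rhythm at a
## subject-specific frequency, focal rhythmic seizure bursts, and three noisy
## annotators whose disagreement is localized at burst boundaries.

#' Configuration of a synthetic EEG cohort
#'
#' @param n_subjects_per_group subjects per group (seizure / non-seizure).
#' @param duration_s recording duration per subject, seconds (>= 2).
#' @param fs sampling rate in Hz (default 256, so that the 256 -> 128 Hz
#'   downsampling path is always exercised).
#' @param burst_rate expected seizure bursts per minute.
#' @param burst_dur_range_s (min, max) burst duration, seconds.
#' @param burst_freq_range_hz (min, max) frequency of the rhythmic discharge,
#'   Hz; must lie within the 0.5-30 Hz physiological band.
#' @param annotator_flip_prob probability that an annotator flips a second
#'   adjacent to a burst boundary.
#' @param amplitude_gain_range (min, max) of the per-subject amplitude gain.
#' @param spectral_tilt_range (min, max) of the 1/f^beta exponent.
#' @param baseline_shift_range_hz (min, max) of the background rhythm peak.
#' @param n_focal_channels_range (min, max) number of focal bipolar channels
#'   for seizure subjects.
#' @param burst_amp_rel burst amplitude relative to the subject's background
#'   RMS.
#' @param baseline_rhythm_rel spectral weight of the background rhythm bump
#'   relative to the 1/f floor.
#' @param base_amp_uv background RMS in microvolts at gain 1.
#' @param seed master integer seed; all randomness derives from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_group = 15,
                          duration_s = 300,
                          fs = 256,
                          burst_rate = 1.5,
                          burst_dur_range_s = c(5, 15),
                          burst_freq_range_hz = c(4, 12),
                          annotator_flip_prob = 0.2,
                          amplitude_gain_range = c(1, 5),
                          spectral_tilt_range = c(0.5, 1.5),
                          baseline_shift_range_hz = c(4, 8),
                          n_focal_channels_range = c(1, 3),
                          burst_amp_rel = 3,
                          baseline_rhythm_rel = 0.8,
                          base_amp_uv = 30,
                          seed = 1L) {
  stopifnot(n_subjects_per_group >= 1, fs > 0, burst_rate >= 0)
  if (duration_s < 2) {
    stop_eegdann("duration_s must be >= 2 s (cannot form one 2-s window)",
                 "eegdann_config_error")
  }
  if (burst_freq_range_hz[1] < 0.5 || burst_freq_range_hz[2] > 30) {
    stop_eegdann("burst_freq_range_hz must lie within [0.5, 30] Hz",
                 "eegdann_config_error")
  }
  if (annotator_flip_prob < 0 || annotator_flip_prob > 1) {
    stop_eegdann("annotator_flip_prob must be in [0, 1]",
                 "eegdann_config_error")
  }
  structure(
    list(
      n_subjects_per_group = as.integer(n_subjects_per_group),
      duration_s = duration_s,
      fs = fs,
      burst_rate = burst_rate,
      burst_dur_range_s = burst_dur_range_s,
      burst_freq_range_hz = burst_freq_range_hz,
      annotator_flip_prob = annotator_flip_prob,
      amplitude_gain_range = amplitude_gain_range,
      spectral_tilt_range = spectral_tilt_range,
      baseline_shift_range_hz = baseline_shift_range_hz,
      n_focal_channels_range = n_focal_channels_range,
      burst_amp_rel = burst_amp_rel,
      baseline_rhythm_rel = baseline_rhythm_rel,
      base_amp_uv = base_amp_uv,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' A synthetic subject's generative profile
#'
#' @param subject_id character identifier.
#' @param amplitude_gain positive scalar multiplier vs. the gain-1 reference.
#' @param spectral_tilt exponent beta of the 1/f^beta background.
#' @param baseline_shift_hz peak frequency of the background rhythm, Hz.
#' @param focal_channels 0-based indices (in `[0, 17]`) of the bipolar channels
#'   carrying seizure bursts; must be non-empty iff `group == "seizure"`.
#' @param group `"seizure"` or `"non_seizure"`.
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id, amplitude_gain, spectral_tilt,
                            baseline_shift_hz, focal_channels,
                            group = c("seizure", "non_seizure")) {
  group <- match.arg(group)
  stopifnot(amplitude_gain > 0)
  focal_channels <- as.integer(focal_channels)
  if (group == "seizure" && length(focal_channels) == 0) {
    stop_eegdann("seizure subjects need at least one focal channel",
                 "eegdann_config_error")
  }
  if (group == "non_seizure" && length(focal_channels) > 0) {
    stop_eegdann("non-seizure subjects must have no focal channels",
                 "eegdann_config_error")
  }
  if (length(focal_channels) > 0 &&
      (min(focal_channels) < 0 || max(focal_channels) > 17)) {
    stop_eegdann("focal_channels must be 0-based indices in [0, 17]",
                 "eegdann_config_error")
  }
  structure(
    list(subject_id = subject_id, amplitude_gain = amplitude_gain,
         spectral_tilt = spectral_tilt, baseline_shift_hz = baseline_shift_hz,
         focal_channels = focal_channels, group = group),
    class = "subject_profile"
  )
}

# Draw a subject profile from the ranges in `config`, deterministically.
sample_subject_profile <- function(config, group, subject_id, seed) {
  with_seed(seed, {
    gain <- runif(1, config$amplitude_gain_range[1],
                  config$amplitude_gain_range[2])
    tilt <- runif(1, config$spectral_tilt_range[1],
                  config$spectral_tilt_range[2])
    base_hz <- runif(1, config$baseline_shift_range_hz[1],
                     config$baseline_shift_range_hz[2])
    focal <- integer(0)
    if (group == "seizure") {
      nf <- sample(config$n_focal_channels_range[1]:
                     config$n_focal_channels_range[2], 1)
      focal <- sort(sample(0:17, nf))
    }
    subject_profile(subject_id, gain, tilt, base_hz, focal, group)
  })
}

# 1/f^beta colored noise with a Gaussian spectral bump at the subject's
# background-rhythm frequency. Each electrode is normalized to exact unit RMS
# before scaling, so background RMS is exactly base_amp_uv * amplitude_gain.
generate_background <- function(profile, config, n_samples, seed) {
  fs <- config$fs
  freqs <- seq(0, fs / 2, by = fs / n_samples)
  # spectral amplitude shape; floor frequency 0.5 Hz avoids a DC blow-up
  f_eff <- pmax(freqs, 0.5)
  shape <- f_eff^(-profile$spectral_tilt / 2) +
    config$baseline_rhythm_rel *
      exp(-(freqs - profile$baseline_shift_hz)^2 / (2 * 1.0^2))
  shape[1] <- 0 # remove DC
  # full (two-sided) spectrum shape, conjugate-symmetric
  n_pos <- length(freqs)
  full <- numeric(n_samples)
  full[seq_len(n_pos)] <- shape
  if (n_samples > n_pos) {
    full[(n_pos + 1):n_samples] <- rev(shape[2:(n_samples - n_pos + 1)])
  }
  sig <- with_seed(seed, {
    white <- matrix(rnorm(19 * n_samples), nrow = 19)
    t(apply(white, 1, function(w) {
      x <- Re(fft(fft(w) * full, inverse = TRUE)) / n_samples
      x / sqrt(mean(x^2))
    }))
  })
  sig * (config$base_amp_uv * profile$amplitude_gain)
}

#' Sample the burst event process for one recording
#'
#' Poisson number of bursts (rate `burst_rate` per minute), uniform start
#' times, durations and discharge frequencies; candidate bursts overlapping an
#' already accepted burst (with a 2.5 s guard margin) are resampled a bounded
#' number of times and then dropped.
#'
#' @param duration_s recording duration in seconds.
#' @param config a [cohort_config()].
#' @param seed integer seed for this event stream.
#' @return data.frame with columns `start_s`, `dur_s`, `freq_hz`.
#' @export
sample_burst_events <- function(duration_s, config, seed) {
  with_seed(seed, {
    n <- rpois(1, config$burst_rate * duration_s / 60)
    ev <- data.frame(start_s = numeric(0), dur_s = numeric(0),
                     freq_hz = numeric(0))
    if (n == 0) return(ev)
    for (i in seq_len(n)) {
      for (try in seq_len(20)) {
        dur <- runif(1, config$burst_dur_range_s[1],
                     min(config$burst_dur_range_s[2], duration_s - 1))
        if (dur <= 0 || dur >= duration_s - 1) next
        start <- runif(1, 0.5, duration_s - dur - 0.5)
        freq <- runif(1, config$burst_freq_range_hz[1],
                      config$burst_freq_range_hz[2])
        ok <- TRUE
        if (nrow(ev) > 0) {
          ok <- all(start > ev$start_s + ev$dur_s + 2.5 |
                      start + dur < ev$start_s - 2.5)
        }
        if (ok) {
          ev <- rbind(ev, data.frame(start_s = start, dur_s = dur,
                                     freq_hz = freq))
          break
        }
      }
    }
    ev[order(ev$start_s), , drop = FALSE]
  })
}

# Hann-ramp on/off envelope (0.5 s ramps), sustained at 1 in between.
burst_envelope <- function(n, fs, ramp_s = 0.5) {
  nr <- min(floor(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[(n - nr + 1):n] <- rev(ramp)
  }
  env
}

#' Generate one subject's synthetic EEG recording
#'
#' Background is subject-gain-scaled colored noise on all 19 electrodes.
#' For seizure-group subjects, rhythmic sinusoid-plus-harmonic bursts are
#' planted on the first electrode of each focal bipolar pair (on the raw
#' electrode signals, so the bipolar derivation is exercised end to end).
#' `truth_mask` marks exactly the seconds overlapped by a burst envelope.
#'
#' @param profile a [subject_profile()].
#' @param config a [cohort_config()].
#' @param seed integer seed for this subject's streams.
#' @return an `eeg_recording`: list with `subject_id`, `signal` (19 x T
#'   microvolt matrix with electrode rownames), `fs`, `annotations` (3 x
#'   T_seconds 0/1 matrix), `truth_mask` (T_seconds 0/1 vector), `group`,
#'   `profile`, and the planted `events` data.frame.
#' @export
generate_subject_recording <- function(profile, config, seed) {
  if (config$duration_s < 2) {
    stop_eegdann("duration_s must be >= 2 s (cannot form one 2-s window)",
                 "eegdann_config_error")
  }
  fs <- config$fs
  n_samples <- floor(config$duration_s * fs)
  t_seconds <- floor(n_samples / fs)
  sig <- generate_background(profile, config, n_samples,
                             derive_seed(seed, 0))
  rownames(sig) <- ELECTRODES_1020
  truth <- integer(t_seconds)
  events <- data.frame(start_s = numeric(0), dur_s = numeric(0),
                       freq_hz = numeric(0))
  if (profile$group == "seizure" && config$burst_rate > 0) {
    events <- sample_burst_events(config$duration_s, config,
                                  derive_seed(seed, 1))
    pairs <- bipolar_pairs()
    plant_electrodes <- unique(pairs[profile$focal_channels + 1, 1])
    amp <- config$burst_amp_rel * config$base_amp_uv * profile$amplitude_gain
    if (nrow(events) > 0) {
      phases <- with_seed(derive_seed(seed, 2),
                          runif(nrow(events), 0, 2 * pi))
      for (i in seq_len(nrow(events))) {
        i0 <- floor(events$start_s[i] * fs) + 1
        n_b <- floor(events$dur_s[i] * fs)
        idx <- i0:(i0 + n_b - 1)
        tt <- (idx - 1) / fs
        f <- events$freq_hz[i]
        wave <- sin(2 * pi * f * tt + phases[i]) +
          0.3 * sin(2 * pi * 2 * f * tt + 2 * phases[i])
        wave <- amp * wave * burst_envelope(n_b, fs)
        for (el in plant_electrodes) {
          sig[el, idx] <- sig[el, idx] + wave
        }
        s0 <- floor(events$start_s[i])
        s1 <- ceiling(events$start_s[i] + events$dur_s[i]) - 1
        s1 <- min(s1, t_seconds - 1)
        truth[(s0:s1) + 1] <- 1L
      }
    }
  }
  ann <- simulate_annotators(truth, config$annotator_flip_prob,
                             derive_seed(seed, 3))
  structure(
    list(subject_id = profile$subject_id, signal = sig, fs = fs,
         annotations = ann, truth_mask = truth, group = profile$group,
         profile = profile, events = events),
    class = "eeg_recording"
  )
}

#' Simulate three noisy annotators from a ground-truth seizure mask
#'
#' Each annotator reproduces the truth except at seconds adjacent to a burst
#' boundary (a second whose truth value differs from a neighbour's), where the
#' label is flipped independently with probability `flip_prob`. This localizes
#' disagreement where clinical experts disagree in practice (event onset and
#' offset).
#'
#' @param truth_mask 0/1 vector of per-second ground truth.
#' @param flip_prob flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a 3 x length(truth_mask) 0/1 matrix (one row per annotator).
#' @export
simulate_annotators <- function(truth_mask, flip_prob, seed) {
  if (flip_prob < 0 || flip_prob > 1) {
    stop_eegdann("flip_prob must be in [0, 1]", "eegdann_config_error")
  }
  n <- length(truth_mask)
  if (n == 0) return(matrix(integer(0), nrow = 3, ncol = 0))
  truth_mask <- as.integer(truth_mask)
  ann <- matrix(rep(truth_mask, each = 3), nrow = 3)
  boundary <- boundary_seconds(truth_mask)
  if (length(boundary) > 0 && flip_prob > 0) {
    flips <- with_seed(seed, {
      matrix(rbinom(3 * length(boundary), 1, flip_prob), nrow = 3)
    })
    ann[, boundary] <- abs(ann[, boundary, drop = FALSE] - flips)
  }
  storage.mode(ann) <- "integer"
  ann
}

# 1-based indices of seconds adjacent to (or at) a truth transition.
boundary_seconds <- function(truth_mask) {
  n <- length(truth_mask)
  if (n < 2) return(integer(0))
  d <- diff(truth_mask) != 0
  which(c(d, FALSE) | c(FALSE, d))
}

#' Generate a full synthetic cohort
#'
#' Produces `2 * n_subjects_per_group` recordings (seizure group ids
#' `sz01, sz02, ...`; non-seizure group ids `ns01, ...`). Profiles and signals
#' are drawn deterministically from `config$seed` via counter-based seed
#' splitting, so any subject can be regenerated independently.
#'
#' @param config a [cohort_config()].
#' @return list of `eeg_recording` objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c("seizure", "non_seizure")
  prefix <- c(seizure = "sz", non_seizure = "ns")
  out <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s%02d", prefix[groups[g]], i)
      prof <- sample_subject_profile(
        config, groups[g], sid, derive_seed(config$seed, g, i, 0)
      )
      out[[sid]] <- generate_subject_recording(
        prof, config, derive_seed(config$seed, g, i, 1)
      )
    }
  }
  out
}

#' Write a cohort to disk as EDF files plus annotation tables
#'
#' Writes one EDF file per subject (standard 10-20 electrode labels),
#' `annotations.csv` (subject_id, second_index, expert1..expert3; seconds are
#' 0-based) and `truth.csv` (subject_id, second_index, truth).
#'
#' @param cohort list of `eeg_recording` objects.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_rows <- list()
  truth_rows <- list()
  for (rec in cohort) {
    write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
    ts <- ncol(rec$annotations)
    ann_rows[[rec$subject_id]] <- data.frame(
      subject_id = rec$subject_id,
      second_index = 0:(ts - 1),
      expert1 = rec$annotations[1, ],
      expert2 = rec$annotations[2, ],
      expert3 = rec$annotations[3, ]
    )
    truth_rows[[rec$subject_id]] <- data.frame(
      subject_id = rec$subject_id,
      second_index = 0:(ts - 1),
      truth = rec$truth_mask
    )
  }
  write.csv(do.call(rbind, ann_rows), file.path(dir, "annotations.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, truth_rows), file.path(dir, "truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
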