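zero_recording <- function(t_samples = 512, fs = 256) {
  sig <- matrix(0, 19, t_samples)
  rownames(sig) <- ELECTRODES_1020
  list(subject_id = "z", signal = sig, fs = fs)
}

test_that("bipolar montage computes pair differences in the fixed order", {
  rec <- zero_recording()
  bp <- derive_bipolar_montage(rec)
  expect_equal(bp$channel_names,
               c("Fp2-F4", "F4-C4", "C4-P4", "P4-O2", "Fp1-F3", "F3-C3",
                 "C3-P3", "P3-O1", "Fp2-F8", "F8-T4", "T4-T6", "T6-O2",
                 "Fp1-F7", "F7-T3", "T3-T5", "T5-O1", "Fz-Cz", "Cz-Pz"))
  expect_equal(dim(bp$signal), c(18, 512))
  expect_true(all(bp$signal == 0))
  # Fp2 = +5 uV: exactly the two channels referencing Fp2 light up
  rec$signal["Fp2", ] <- 5
  bp <- derive_bipolar_montage(rec)
  expect_equal(unname(bp$signal["Fp2-F4", ]), rep(5, 512))
  expect_equal(unname(bp$signal["Fp2-F8", ]), rep(5, 512))
  others <- setdiff(bp$channel_names, c("Fp2-F4", "Fp2-F8"))
  expect_true(all(bp$signal[others, ] == 0))
  # electrode labels are matched case-insensitively
  rownames(rec$signal) <- toupper(rownames(rec$signal))
  expect_silent(derive_bipolar_montage(rec))
})

test_that("missing electrodes raise a montage error naming them", {
  rec <- zero_recording()
  rownames(rec$signal)[rownames(rec$signal) == "Cz"] <- "XX"
  err <- expect_error(derive_bipolar_montage(rec),
                      class = "eegdann_montage_error")
  expect_match(conditionMessage(err), "Cz")
})

test_that("downsampling halves length, keeps DC and passband amplitude", {
  rec <- zero_recording(t_samples = 2560)
  bp <- derive_bipolar_montage(rec)
  bp$signal[] <- 3.7 # DC
  ds <- downsample_signal(bp)
  expect_equal(ds$fs, 128)
  expect_equal(ncol(ds$signal), 1280)
  interior <- 100:1180
  expect_equal(unname(ds$signal[1, interior]), rep(3.7, length(interior)),
               tolerance = 1e-6)
  # 10 Hz sinusoid: amplitude preserved within 1%
  t <- (0:2559) / 256
  bp$signal <- matrix(rep(sin(2 * pi * 10 * t), each = 18), nrow = 18)
  rownames(bp$signal) <- bp$channel_names
  ds <- downsample_signal(bp)
  t2 <- (0:1279) / 128
  ref <- sin(2 * pi * 10 * t2)
  expect_lt(max(abs(ds$signal[1, interior] - ref[interior])), 0.01)
  # non-256 Hz input is rejected
  bp$fs <- 200
  expect_error(downsample_signal(bp), class = "eegdann_rate_error")
})

test_that("window segmentation follows role-specific strides and drops tails", {
  sig <- matrix(rnorm(18 * 128 * 10), 18)
  bp <- structure(list(signal = sig, fs = 128,
                       channel_names = bipolar_channel_names()),
                  class = "bipolar_recording")
  ct <- list(consensus = rep(0L, 10), disagreement = rep(0L, 10),
             subject_id = "s")
  wt <- segment_windows(bp, ct, "train", "s")
  we <- segment_windows(bp, ct, "eval", "s")
  expect_equal(dim(wt$windows), c(9, 18, 256))
  expect_equal(dim(we$windows), c(5, 18, 256))
  expect_equal(wt$start_times_s, 0:8)
  expect_equal(we$start_times_s, c(0, 2, 4, 6, 8))
  # window content is the raw samples
  expect_equal(wt$windows[3, , ], sig[, 257:512])
})

test_that("window labels come from the central second", {
  bp <- structure(list(signal = matrix(0, 18, 128 * 10), fs = 128,
                       channel_names = bipolar_channel_names()),
                  class = "bipolar_recording")
  cons <- c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L) # second 5 is seizure
  ct <- list(consensus = cons, disagreement = integer(10), subject_id = "s")
  wt <- segment_windows(bp, ct, "train", "s")
  # window [4, 6) has central second 5 -> label 1; [5, 7) has center 6 -> 0
  expect_equal(wt$labels, as.integer(0:8 + 1 == 5))
})

test_that("recordings shorter than a window give an empty set with warning", {
  bp <- structure(list(signal = matrix(0, 18, 128), fs = 128,
                       channel_names = bipolar_channel_names()),
                  class = "bipolar_recording")
  ct <- list(consensus = c(0L), disagreement = c(0L), subject_id = "s")
  expect_warning(ws <- segment_windows(bp, ct, "eval", "s"), "shorter")
  expect_equal(dim(ws$windows)[1], 0)
})

test_that("STFT produces the 33 x 17 log-magnitude contract", {
  p <- stft_params()
  expect_equal(p$freq_res_hz, 2)
  ws <- random_window_set(n = 3)
  sp <- stft_logmag(ws)
  expect_equal(dim(sp$tensor), c(3, 18, 33, 17))
  expect_false(sp$normalized)
  # pure 8 Hz unit sinusoid peaks at frequency bin index 4 (0-based)
  t <- (0:255) / 128
  ws$windows[1, 1, ] <- sin(2 * pi * 8 * t)
  sp <- stft_logmag(ws)
  interior_frames <- 3:15
  peaks <- apply(sp$tensor[1, 1, , interior_frames], 2, which.max) - 1L
  expect_true(all(peaks == 4L))
  # log floor guards all-zero windows
  ws$windows[2, , ] <- 0
  expect_true(all(is.finite(stft_logmag(ws)$tensor)))
})

test_that("spectrogram energy grows monotonically with input amplitude", {
  ws <- random_window_set(n = 1, seed = 5)
  energies <- vapply(c(1, 2, 4), function(a) {
    w <- ws
    w$windows <- w$windows * a
    sum(exp(stft_logmag(w)$tensor)^2)
  }, 0)
  expect_true(all(diff(energies) > 0))
})

test_that("z-score normalization hits (0, 1) on train and guards leakage", {
  ws <- random_window_set(n = 8, seed = 2, subject_ids = rep(c("a", "b"), 4))
  sp <- stft_logmag(ws)
  spn <- zscore_normalize(sp)
  expect_lt(abs(mean(spn$tensor)), 1e-5)
  expect_lt(abs(sd(as.vector(spn$tensor)) - 1), 1e-5)
  expect_true(spn$normalized)
  # location invariance: a constant shift normalizes to the same tensor
  sp_shift <- sp
  sp_shift$tensor <- sp$tensor + 3
  expect_equal(zscore_normalize(sp_shift)$tensor, spn$tensor,
               tolerance = 1e-12)
  # eval batch normalized with train stats differs from self-normalization
  we <- random_window_set(n = 4, seed = 9, role = "eval",
                          subject_ids = rep("c", 4))
  se <- stft_logmag(we)
  se$tensor <- se$tensor * 2 + 1
  stats <- fit_zscore_stats(sp)
  with_train_stats <- apply_zscore(se, stats)
  self_stats <- fit_zscore_stats(
    structure(modifyList(se, list(split_role = "train")),
              class = "spectrogram_batch"))
  with_self_stats <- apply_zscore(se, self_stats, check_leakage = FALSE)
  expect_gt(max(abs(with_train_stats$tensor - with_self_stats$tensor)), 0.1)
  # leakage: applying train-fitted stats to an eval batch sharing subjects
  we_leak <- random_window_set(n = 2, seed = 1, role = "eval",
                               subject_ids = c("a", "x"))
  expect_error(apply_zscore(stft_logmag(we_leak), stats),
               class = "eegdann_leakage_error")
  # degenerate input
  sp0 <- sp
  sp0$tensor[] <- 1
  expect_error(fit_zscore_stats(sp0), class = "eegdann_degenerate_error")
  # stats must come from training-role data
  expect_error(fit_zscore_stats(se), class = "eegdann_leakage_error")
})

test_that("end-to-end shape pipeline holds for any recording >= 2 s", {
  cohort <- tiny_cohort()
  rec <- cohort[[1]]
  ws <- preprocess_recording(rec, "train")
  expect_equal(dim(ws$windows)[2:3], c(18, 256))
  sp <- stft_logmag(ws)
  expect_equal(dim(sp$tensor)[2:4], c(18, 33, 17))
  expect_equal(dim(sp$tensor)[1], dim(ws$windows)[1])
})
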