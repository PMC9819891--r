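# Sub-band scheme, band decomposition, Welch PSD, average log-PSD, and the
# per-channel band-power feature vector.

test_that("sub-band scheme reproduces the canonical 128 Hz decomposition", {
  s <- subband_ranges(128, 5)
  expect_identical(s$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_identical(s$level_label, c("A4", "D4", "D3", "D2", "D1"))
  expect_identical(s$f_low, c(1, 4, 8, 16, 32))
  expect_identical(s$f_high, c(4, 8, 16, 32, 64))
})

test_that("sub-band scheme is a contiguous partition up to Nyquist", {
  s256 <- subband_ranges(256, 5)
  expect_identical(s256$f_high, c(8, 16, 32, 64, 128))
  for (fs in c(100, 128, 250, 512)) {
    s <- subband_ranges(fs, 5)
    expect_identical(s$f_low[-1], s$f_high[-5])
    expect_identical(s$f_high[5], fs / 2)
  }
  expect_error(subband_ranges(16, 5), "dyadic")
})

test_that("band decomposition is additive and localizes tones", {
  fs <- 128
  for (seed in c(1, 2, 3)) {
    x <- with_test_seed(seed, rnorm(with_test_seed(seed + 50, sample(150:1200, 1))))
    b <- wavelet_band_decompose(x, fs)
    expect_length(b, 5)
    expect_equal(Reduce(`+`, b), x, tolerance = 1e-6)
  }
  x10 <- sine_wave(10, fs, 8)
  e10 <- vapply(wavelet_band_decompose(x10, fs), function(s) sum(s^2), numeric(1))
  expect_gte(e10[["alpha"]] / sum(e10), 0.8)
  x50 <- sine_wave(50, fs, 8)
  e50 <- vapply(wavelet_band_decompose(x50, fs), function(s) sum(s^2), numeric(1))
  expect_identical(names(which.max(e50)), "gamma")
  expect_error(wavelet_band_decompose(rnorm(50), fs), "too short")
})

test_that("Welch PSD finds tone peaks and is flat on white noise", {
  fs <- 128
  p0 <- welch_psd(numeric(300) + 0, fs)
  expect_true(all(p0$Pxx == 0))
  expect_identical(p0$P, length(p0$Pxx))
  p <- welch_psd(sine_wave(10, fs, 16), fs)
  bin <- diff(p$freqs[1:2])
  expect_lte(abs(p$freqs[which.max(p$Pxx)] - 10), bin)
  z <- with_test_seed(410, rnorm(60 * fs))
  pz <- welch_psd(z, fs)
  in_band <- pz$freqs >= 4 & pz$freqs <= 45
  thirds <- cut(pz$freqs[in_band], 3)
  band_means <- tapply(pz$Pxx[in_band], thirds, mean)
  expect_true(all(abs(band_means / mean(pz$Pxx[in_band]) - 1) < 0.2))
  expect_error(welch_psd(numeric(0), fs), "length")
})

test_that("average log-PSD matches the direct-summation oracle", {
  expect_equal(avg_log_psd(list(Pxx = rep(1, 10))), 0)
  expect_equal(avg_log_psd(list(Pxx = rep(100, 7))), 20)
  Pxx <- with_test_seed(411, runif(257, 1e-8, 10))
  oracle <- 0
  for (v in Pxx) oracle <- oracle + 10 * log10(v)
  oracle <- oracle / length(Pxx)
  expect_equal(avg_log_psd(list(Pxx = Pxx)), oracle, tolerance = 1e-12)
  # zeros are floored, not -Inf
  expect_true(is.finite(avg_log_psd(list(Pxx = c(0, 1)))))
})

test_that("feature vector has the channel-major band-minor contract", {
  spec <- eeg_sim_spec(n_classes = 2, trials_per_class = 1, n_channels = 32,
                       duration_s = 5, seed = 21)
  rec <- simulate_eeg(spec)$recordings[[1]]
  f <- extract_eeg_features(rec)
  expect_length(f, 32 * 4)
  expect_identical(names(f)[1:4], paste0(montage_32()[1], "_",
                                         c("theta", "alpha", "beta", "gamma")))
  expect_identical(extract_eeg_features(rec), f)  # deterministic
  expect_error(extract_eeg_features(rec, bands = "sigma"), "unknown band")
})

test_that("an isolated alpha oscillation yields a maximal alpha feature", {
  amp <- matrix(rep(c(0, 5, 0, 0), each = 2), 2, 4)
  spec <- eeg_sim_spec(n_classes = 2, trials_per_class = 1, n_channels = 2,
                       duration_s = 10, band_amplitudes = amp,
                       noise_sigma = 0.2, seed = 11)
  rec <- simulate_eeg(spec)$recordings[[1]]
  f <- extract_eeg_features(rec)[1:4]
  expect_identical(names(which.max(f)), "ch1_alpha")
})

test_that("feature values follow the 20 dB power-scaling law", {
  spec <- eeg_sim_spec(n_classes = 2, trials_per_class = 1, n_channels = 2,
                       duration_s = 8, seed = 22)
  rec <- simulate_eeg(spec)$recordings[[1]]
  f1 <- extract_eeg_features(rec)
  rec10 <- rec
  rec10$samples <- rec$samples * 10
  f10 <- extract_eeg_features(rec10)
  expect_true(all(abs((f10 - f1) - 20) < 0.5))
})
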