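# Stereo merge, clip segmentation, and the nine audio feature families.

test_that("stereo merge is the element-wise mean", {
  x <- with_test_seed(601, rnorm(1000))
  expect_identical(merge_stereo(x, x), x)
  expect_identical(merge_stereo(x, -x), numeric(1000))
  y <- with_test_seed(602, rnorm(1000))
  expect_identical(merge_stereo(x, y), (x + y) / 2)
  expect_error(merge_stereo(x, y[-1]), "lengths differ")
})

test_that("segmentation truncates to whole 15 s clips", {
  fs <- 44100
  expect_length(segment_clips(numeric(60 * fs)), 4)
  expect_length(segment_clips(numeric(round(59.9 * fs))), 3)
  expect_length(segment_clips(numeric(14 * fs)), 0)
  clips <- segment_clips(seq_len(40 * fs) / (40 * fs), source_id = "s")
  expect_length(clips, 2)
  expect_identical(vapply(clips, function(cl) cl$clip_index, integer(1)), 0:1)
  # disjoint, ordered, total length bounded by the input
  expect_identical(clips[[1]]$samples, seq_len(15 * fs) / (40 * fs))
  expect_equal(clips[[2]]$samples, seq_len(15 * fs) / (40 * fs) + 15 / 40)
  expect_lte(sum(vapply(clips, function(cl) length(cl$samples), numeric(1))),
             40 * fs)
})

test_that("RMS and zero crossings match closed forms", {
  expect_equal(rms(rep(0.5, 100)), 0.5)
  expect_equal(rms(numeric(100) + 0), 0)
  expect_equal(rms(sine_wave(100, 44100, 1)), 1 / sqrt(2), tolerance = 1e-3)
  expect_identical(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_identical(zero_crossings(rep(0.3, 50)), 0)
  # f Hz sine over T seconds crosses ~2 f T times
  zc <- zero_crossings(audio_clip(sine_wave(440, 44100, 2, amp = 0.9)))
  expect_lte(abs(zc - 2 * 440 * 2), 2)
  x <- with_test_seed(603, rnorm(500))
  expect_lte(zero_crossings(audio_clip(x / max(abs(x)))), 499)
})

test_that("spectral centroid tracks tone frequency and weighted mixtures", {
  expect_equal(spectral_centroid(audio_clip(sine_wave(1000, 44100, 2, 0.5))),
               1000, tolerance = 20)
  expect_equal(spectral_centroid(audio_clip(sine_wave(5000, 44100, 2, 0.5))),
               5000, tolerance = 50)
  two <- (sine_wave(400, 44100, 2) + sine_wave(1200, 44100, 2)) / 2.5
  expect_equal(spectral_centroid(audio_clip(two)), 800, tolerance = 30)
  expect_identical(spectral_centroid(audio_clip(numeric(44100) + 0)), 0)
})

test_that("spectral flux vanishes for stationary frames, matches its oracle", {
  expect_lt(spectral_flux(audio_clip(sine_wave(1000, 44100, 2, 0.5))), 1e-6)
  # alternating tone / silence blocks produce strictly positive flux
  alt <- rep(c(sine_wave(800, 44100, 0.25, 0.5), numeric(11025)), 4)
  expect_gt(spectral_flux(audio_clip(alt)), 1e-3)
  # brute-force frame-pair oracle on seeded noise
  x <- with_test_seed(604, rnorm(44100)) * 0.2
  clip <- audio_clip(x)
  st <- emomap:::stft_mag(x, 44100)
  fluxes <- numeric(st$n_frames - 1)
  for (i in 2:st$n_frames) {
    a <- st$mag[i - 1, ] / sqrt(sum(st$mag[i - 1, ]^2))
    b <- st$mag[i, ] / sqrt(sum(st$mag[i, ]^2))
    fluxes[i - 1] <- sum((b - a)^2)
  }
  expect_equal(spectral_flux(clip), mean(fluxes), tolerance = 1e-10)
})

test_that("MFCCs are finite on silence and deterministic", {
  sil <- mfcc(audio_clip(numeric(44100 * 2) + 0))
  expect_length(sil, 13)
  expect_true(all(is.finite(sil)))
  x <- with_test_seed(605, rnorm(44100))
  x <- x / max(abs(x)) * 0.3
  expect_identical(mfcc(audio_clip(x)), mfcc(audio_clip(x)))
  # brute-force per-frame re-derivation of the filterbank/DCT pipeline
  clip <- audio_clip(x)
  st <- emomap:::stft_mag(x, 44100)
  fb <- emomap:::mel_filterbank(st$bin_freqs, 26)
  acc <- numeric(13)
  for (i in seq_len(st$n_frames)) {
    E <- log(pmax(as.numeric(fb %*% st$mag[i, ]^2), 1e-10))
    for (n in 1:13) acc[n] <- acc[n] + sum(E * cos(pi * n * ((1:26) - 0.5) / 26))
  }
  expect_equal(unname(mfcc(clip)), acc / st$n_frames, tolerance = 1e-9)
})

test_that("tempo recovery is within 2 BPM on click tracks", {
  for (bpm in c(60, 90, 120, 150, 180)) {
    r <- estimate_bpm(audio_clip(click_track(bpm)))
    expect_lte(abs(r$bpm - bpm), 2)
    expect_gt(r$bpm_intensity, 0.5)
  }
  noise <- with_test_seed(606, rnorm(15 * 44100)) * 0.1
  r_noise <- estimate_bpm(audio_clip(noise))
  r_click <- estimate_bpm(audio_clip(click_track(120)))
  expect_lt(r_noise$bpm_intensity, r_click$bpm_intensity)
  sil <- estimate_bpm(audio_clip(numeric(15 * 44100) + 0))
  expect_true(sil$degenerate)
  expect_identical(sil$bpm_intensity, 0)
  expect_equal(sil$bpm, 120)
})

test_that("mode score sign separates major and minor triads", {
  expect_gt(estimate_mode(triad_clip(60)), 0)            # C major (C4 E4 G4)
  expect_lt(estimate_mode(triad_clip(57, minor = TRUE)), 0)  # A minor (A3 C4 E4)
  noise <- audio_clip(with_test_seed(607, rnorm(4 * 44100)) * 0.1)
  expect_lt(abs(estimate_mode(noise)), abs(estimate_mode(triad_clip(60))))
  expect_lt(abs(estimate_mode(noise)),
            abs(estimate_mode(triad_clip(57, minor = TRUE))))
  expect_identical(estimate_mode(audio_clip(numeric(44100) + 0)), 0)
})

test_that("roughness follows the dissonance-curve ordering", {
  r_beat <- roughness(tone_pair(440, 460))
  r_octave <- roughness(tone_pair(440, 880))
  r_pure <- roughness(audio_clip(sine_wave(440, 44100, 4, 0.8)))
  expect_gt(r_beat, r_octave)
  expect_lt(r_pure, 0.01 * r_beat)
  expect_identical(roughness(audio_clip(numeric(44100) + 0)), 0)
  expect_gte(r_octave, 0)
})

test_that("the music feature vector has the 21-value contract", {
  clip <- simulate_music(audio_sim_spec(clips_per_class = 1, seed = 31))$clips[[5]]
  v <- extract_music_features(clip)
  expect_length(v, 21)
  expect_identical(names(v),
                   c(paste0("mfcc_", 1:13), "spectral_centroid", "spectral_flux",
                     "zero_crossings", "rms", "bpm", "bpm_intensity", "mode",
                     "roughness"))
  expect_identical(extract_music_features(clip), v)
  expect_true(all(is.finite(v)))
  expect_gte(v[["rms"]], 0)
  expect_true(v[["bpm"]] >= 60 && v[["bpm"]] <= 180)
})
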