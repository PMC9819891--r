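# Seeded generators with known ground truth: band-limited oscillatory EEG
# with class-dependent band powers, music clips with controlled tempo /
# spectral tilt / triad mode / beating-partial roughness, and transition
# records drawn from a known conditional matrix. Each generator is a pure
# function of its spec (including the seed).

#' Specification for synthetic EEG
#'
#' Each trial is a sum of band-limited sinusoids (theta 6 Hz, alpha 10 Hz,
#' beta 24 Hz, gamma 38 Hz — all inside the 4-45 Hz pass band) with random
#' phase and class-dependent amplitude on the informative channels, plus
#' white Gaussian noise. The default profile boosts one band per class by a
#' 3:1 amplitude ratio against a 1 uV base, with unit noise.
#'
#' @param n_classes number of emotion classes (default 4).
#' @param trials_per_class trials per class (default 40).
#' @param n_channels channels (default 32, the [montage_32()] layout).
#' @param fs sampling rate in Hz (default 128).
#' @param duration_s trial length in seconds (default 10).
#' @param band_amplitudes `n_classes x 4` matrix of theta/alpha/beta/gamma
#'   amplitudes in uV; default boosts band `(k - 1) %% 4 + 1` for class `k`.
#' @param informative_channels channel indices carrying the class signal
#'   (default all).
#' @param noise_sigma Gaussian noise SD in uV (default 1).
#' @param seed RNG seed.
#' @return An `"eeg_sim_spec"` list.
#' @export
eeg_sim_spec <- function(n_classes = 4, trials_per_class = 40, n_channels = 32,
                         fs = 128, duration_s = 10, band_amplitudes = NULL,
                         informative_channels = seq_len(n_channels),
                         noise_sigma = 1, seed = 1) {
  check_scalar(n_classes, "n_classes", lower = 2)
  check_scalar(trials_per_class, "trials_per_class", lower = 1)
  check_scalar(n_channels, "n_channels", lower = 1)
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  check_scalar(duration_s, "duration_s", lower = 0, strict = TRUE)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  if (is.null(band_amplitudes)) {
    band_amplitudes <- matrix(1, n_classes, 4)
    for (k in seq_len(n_classes)) band_amplitudes[k, (k - 1) %% 4 + 1] <- 3
  }
  band_amplitudes <- as.matrix(band_amplitudes)
  if (!all(dim(band_amplitudes) == c(n_classes, 4)))
    stop_input("'band_amplitudes' must be %d x 4", n_classes)
  if (any(band_amplitudes < 0)) stop_input("'band_amplitudes' must be >= 0")
  informative_channels <- as.integer(informative_channels)
  if (any(informative_channels < 1 | informative_channels > n_channels))
    stop_input("'informative_channels' must lie in [1, %d]", n_channels)
  colnames(band_amplitudes) <- c("theta", "alpha", "beta", "gamma")
  structure(list(n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, band_amplitudes = band_amplitudes,
                 informative_channels = informative_channels,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "eeg_sim_spec")
}

BAND_CENTER_HZ <- c(theta = 6, alpha = 10, beta = 24, gamma = 38)

#' Simulate EEG recordings with known band-power structure
#'
#' @param spec an [eeg_sim_spec()].
#' @return List with `recordings` (list of [eeg_recording()]), `labels`
#'   (factor `class1` ...), and `spec` (the ground truth).
#' @export
simulate_eeg <- function(spec) {
  if (!inherits(spec, "eeg_sim_spec")) stop_input("'spec' must be an eeg_sim_spec")
  n <- round(spec$fs * spec$duration_s)
  t <- seq_len(n) / spec$fs
  ch_names <- if (spec$n_channels == 32) montage_32()
              else paste0("ch", seq_len(spec$n_channels))
  labels <- rep(paste0("class", seq_len(spec$n_classes)),
                each = spec$trials_per_class)
  recordings <- with_seed(spec$seed, {
    lapply(seq_along(labels), function(i) {
      k <- (i - 1) %/% spec$trials_per_class + 1
      mat <- matrix(0, spec$n_channels, n)
      for (ch in seq_len(spec$n_channels)) {
        amps <- if (ch %in% spec$informative_channels) spec$band_amplitudes[k, ]
                else rep(1, 4)
        phases <- stats::runif(4, 0, 2 * pi)
        sig <- colSums(amps * sin(outer(2 * pi * BAND_CENTER_HZ, t) + phases))
        mat[ch, ] <- sig + stats::rnorm(n, sd = spec$noise_sigma)
      }
      eeg_recording(mat, fs = spec$fs, channel_names = ch_names,
                    trial_id = sprintf("trial%03d", i))
    })
  })
  list(recordings = recordings, labels = factor(labels), spec = spec)
}

#' Specification for synthetic music clips
#'
#' Each clip is a click train at the class tempo, a triad (major or minor per
#' class, with two harmonics per chord tone), spectrally tilted noise, and —
#' for rough classes — a partner partial detuned from the triad root by a
#' few tens of Hz to create beating. The default class profiles span the
#' eight music emotion labels with distinct tempo / tilt / mode / roughness /
#' level combinations, so every feature family separates at least one pair.
#'
#' @param profiles data frame with columns `label`, `tempo` (beats/min,
#'   within 60-180), `tilt` (spectral tilt of the noise bed, dB/octave),
#'   `minor` (logical), `detune` (Hz, 0 = no beating partial), `level`
#'   (peak level in `[0, 1]`); default: one row per music emotion.
#' @param clips_per_class clips per class (default 40).
#' @param duration_s clip length (default 15 s).
#' @param fs sampling rate (default 44100).
#' @param seed RNG seed.
#' @return An `"audio_sim_spec"` list.
#' @export
audio_sim_spec <- function(profiles = NULL, clips_per_class = 40,
                           duration_s = 15, fs = 44100, seed = 1) {
  if (is.null(profiles)) {
    profiles <- data.frame(
      label = c("anger", "confidence", "disgust", "fear", "joy", "passion",
                "relaxation", "sadness"),
      tempo = c(152, 120, 132, 96, 126, 140, 72, 64),
      tilt = c(1, -1, 2, 0, -2, -1.5, -5, -4),
      minor = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
      detune = c(24, 0, 30, 18, 0, 8, 0, 0),
      level = c(0.85, 0.7, 0.9, 0.5, 0.75, 0.8, 0.35, 0.4),
      stringsAsFactors = FALSE)
  }
  need <- c("label", "tempo", "tilt", "minor", "detune", "level")
  if (!all(need %in% colnames(profiles)))
    stop_input("'profiles' must have columns %s", paste(need, collapse = ", "))
  if (any(profiles$tempo < 60 | profiles$tempo > 180))
    stop_input("profile tempo must lie in [60, 180] BPM")
  if (any(profiles$level < 0 | profiles$level > 1))
    stop_input("profile level must lie in [0, 1]")
  check_scalar(clips_per_class, "clips_per_class", lower = 1)
  structure(list(profiles = profiles, clips_per_class = as.integer(clips_per_class),
                 duration_s = duration_s, fs = as.integer(fs),
                 seed = as.integer(seed)),
            class = "audio_sim_spec")
}

# One synthesized clip for a profile row; called inside the generator's
# seeded RNG scope.
synth_clip_samples <- function(p, duration_s, fs) {
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  # click train: 5 ms Hann-windowed 1 kHz bursts on the beat grid
  x <- numeric(n)
  burst_n <- round(0.005 * fs)
  burst <- sin(2 * pi * 1000 * seq_len(burst_n) / fs) *
    (0.5 - 0.5 * cos(2 * pi * seq_len(burst_n) / burst_n))
  phase <- stats::runif(1, 0, 60 / p$tempo / 2)
  beat_times <- seq(phase, duration_s - 0.01, by = 60 / p$tempo)
  for (bt in beat_times) {
    i <- round(bt * fs) + 1L
    j <- min(i + burst_n - 1L, n)
    x[i:j] <- x[i:j] + burst[seq_len(j - i + 1L)]
  }
  # triad with two harmonics per tone, random root in octave 4
  root_midi <- sample(60:71, 1)
  f0 <- 440 * 2^((root_midi - 69) / 12)
  intervals <- if (p$minor) c(0, 3, 7) else c(0, 4, 7)
  freqs <- f0 * 2^(intervals / 12)
  triad <- numeric(n)
  for (fr in freqs) {
    for (h in 1:3) {
      ph <- stats::runif(1, 0, 2 * pi)
      triad <- triad + (0.5 / h) * sin(2 * pi * fr * h * t + ph)
    }
  }
  triad <- triad / max(abs(triad)) * 0.45
  # beating partner partial near the root
  rough <- if (p$detune > 0) 0.4 * sin(2 * pi * (f0 + p$detune) * t +
                                         stats::runif(1, 0, 2 * pi)) else 0
  # tilted noise bed: white noise shaped by (f/1000)^(tilt/6.02) in dB terms
  noise <- stats::rnorm(n)
  spec_gain <- function(f) ifelse(f <= 0, 0, 10^((p$tilt * log2(f / 1000)) / 20))
  nf <- stats::fft(noise)
  freqs_fft <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  noise <- Re(stats::fft(nf * spec_gain(freqs_fft), inverse = TRUE)) / n
  noise <- noise / max(abs(noise)) * 0.12
  mix <- 0.8 * x + triad + rough + noise
  mix / max(abs(mix)) * p$level
}

#' Simulate labelled music clips
#'
#' @param spec an [audio_sim_spec()].
#' @param dir optional directory; when given, each clip is written as a
#'   float32 WAV (`<label>_<i>.wav`) with a `manifest.json` of the ground
#'   truth.
#' @return List with `clips` (list of [audio_clip()]), `labels` (factor),
#'   and `spec`.
#' @export
simulate_music <- function(spec, dir = NULL) {
  if (!inherits(spec, "audio_sim_spec")) stop_input("'spec' must be an audio_sim_spec")
  pr <- spec$profiles
  labels <- rep(pr$label, each = spec$clips_per_class)
  clips <- with_seed(spec$seed, {
    lapply(seq_along(labels), function(i) {
      k <- (i - 1) %/% spec$clips_per_class + 1
      idx <- (i - 1) %% spec$clips_per_class
      audio_clip(synth_clip_samples(pr[k, ], spec$duration_s, spec$fs),
                 fs = spec$fs, source_id = pr$label[k], clip_index = idx)
    })
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(length(clips))
    for (i in seq_along(clips)) {
      files[i] <- file.path(dir, sprintf("%s_%03d.wav", labels[i],
                                         clips[[i]]$clip_index))
      write_wav(clips[[i]]$samples, files[i], fs = spec$fs, format = "float")
    }
    jsonlite::write_json(list(labels = labels, files = basename(files),
                              profiles = pr, seed = spec$seed),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(clips = clips, labels = factor(labels, levels = pr$label), spec = spec)
}

#' Specification for synthetic transition records
#'
#' @param matrix data frame with columns `before`, `music_type`, `after`,
#'   `probability`; within each `(before, music_type)` key the probabilities
#'   must sum to 1.
#' @param n_records number of records to draw (keys sampled uniformly).
#' @param seed RNG seed.
#' @return A `"transition_sim_spec"` list.
#' @export
transition_sim_spec <- function(matrix, n_records = 5000, seed = 1) {
  need <- c("before", "music_type", "after", "probability")
  if (!is.data.frame(matrix) || !all(need %in% colnames(matrix)))
    stop_input("'matrix' must be a data frame with columns %s",
               paste(need, collapse = ", "))
  key <- interaction(matrix$before, matrix$music_type, drop = TRUE)
  sums <- tapply(matrix$probability, key, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop_input("conditional probabilities must sum to 1 per (before, music_type); worst key off by %g",
               max(abs(sums - 1)))
  check_scalar(n_records, "n_records", lower = 1)
  structure(list(matrix = matrix[need], n_records = as.integer(n_records),
                 seed = as.integer(seed)),
            class = "transition_sim_spec")
}

#' A dense random conditional transition matrix
#'
#' Normalized uniform draws: a convenient known ground truth for recovery
#' experiments.
#'
#' @param before,music_type,after label vocabularies.
#' @param seed RNG seed.
#' @return Data frame usable as the `matrix` of [transition_sim_spec()].
#' @export
random_transition_matrix <- function(before, music_type,
                                     after = before, seed = 1) {
  grid <- expand.grid(before = before, music_type = music_type, after = after,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$before, grid$music_type, grid$after), ]
  rownames(grid) <- NULL
  with_seed(seed, {
    u <- stats::runif(nrow(grid), 0.2, 1)
    key <- interaction(grid$before, grid$music_type, drop = TRUE)
    tot <- tapply(u, key, sum)
    grid$probability <- u / as.numeric(tot[key])
  })
  grid
}

#' Simulate emotion-transition records
#'
#' Draws records i.i.d.: the `(before, music_type)` key uniformly over the
#' keys of the matrix, then `after` from the conditional distribution.
#'
#' @param spec a [transition_sim_spec()].
#' @return Data frame with columns `before`, `music_type`, `after`.
#' @export
simulate_transitions <- function(spec) {
  if (!inherits(spec, "transition_sim_spec")) stop_input("'spec' must be a transition_sim_spec")
  m <- spec$matrix
  keys <- unique(m[c("before", "music_type")])
  with_seed(spec$seed, {
    ki <- sample.int(nrow(keys), spec$n_records, replace = TRUE)
    after <- vapply(ki, function(i) {
      rows <- m$before == keys$before[i] & m$music_type == keys$music_type[i]
      sample(m$after[rows], 1, prob = m$probability[rows])
    }, character(1))
    data.frame(before = keys$before[ki], music_type = keys$music_type[ki],
               after = after, stringsAsFactors = FALSE)
  })
}
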