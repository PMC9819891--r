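# Signal builders shared across tests. All synthetic; every stochastic
# construction takes an explicit seed.

sine_wave <- function(freq, fs, duration_s, amp = 1) {
  amp * sin(2 * pi * freq * seq_len(round(fs * duration_s)) / fs)
}

noisy_sine <- function(freq, fs, duration_s, snr_db, seed) {
  clean <- sine_wave(freq, fs, duration_s)
  noise <- with_test_seed(seed, rnorm(length(clean)))
  noise <- noise * sqrt(mean(clean^2) / (10^(snr_db / 10) * mean(noise^2)))
  list(clean = clean, noisy = clean + noise)
}

snr_db <- function(clean, est) 10 * log10(mean(clean^2) / mean((est - clean)^2))

# 5 ms Hann-windowed 1 kHz bursts on a strict beat grid.
click_track <- function(bpm, fs = 44100, duration_s = 15, amp = 0.8) {
  x <- numeric(round(duration_s * fs))
  bn <- round(0.005 * fs)
  burst <- amp * sin(2 * pi * 1000 * seq_len(bn) / fs) *
    (0.5 - 0.5 * cos(2 * pi * seq_len(bn) / bn))
  for (bt in seq(0, duration_s - 0.01, by = 60 / bpm)) {
    i <- round(bt * fs) + 1L
    x[i:(i + bn - 1L)] <- x[i:(i + bn - 1L)] + burst
  }
  pmax(pmin(x, 1), -1)
}

# Pure-sine triad rooted at a MIDI note.
triad_clip <- function(root_midi, minor = FALSE, fs = 44100, duration_s = 4) {
  f0 <- 440 * 2^((root_midi - 69) / 12)
  freqs <- f0 * 2^((if (minor) c(0, 3, 7) else c(0, 4, 7)) / 12)
  x <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * seq_len(round(fs * duration_s)) / fs)))
  audio_clip(x / max(abs(x)) * 0.8, fs = fs)
}

tone_pair <- function(f1, f2, fs = 44100, duration_s = 4) {
  n <- round(fs * duration_s)
  x <- sin(2 * pi * f1 * seq_len(n) / fs) + sin(2 * pi * f2 * seq_len(n) / fs)
  audio_clip(x / 2.2, fs = fs)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
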