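# The 21-dimensional per-clip audio feature vector: 13 MFCCs plus spectral
# centroid, spectral flux, zero crossings, RMS, tempo (BPM) and pulse
# clarity, a major/minor mode score, and sensory roughness.
#
# Analysis configuration (constants, documented here once):
#  - generic STFT: 2048-sample frames, hop 1024, Hann window;
#  - onset/tempo STFT: 1024-sample frames, hop 256;
#  - chroma STFT: 8192-sample frames, hop 4096 (semitone resolution above C3);
#  - roughness STFT: 16384-sample frames, hop 8192 (resolves beating partials
#    ~10-30 Hz apart).

MUSIC_FEATURE_NAMES <- c(paste0("mfcc_", 1:13), "spectral_centroid",
                         "spectral_flux", "zero_crossings", "rms",
                         "bpm", "bpm_intensity", "mode", "roughness")

MUSIC_EMOTIONS <- c("anger", "confidence", "disgust", "fear", "joy",
                    "passion", "relaxation", "sadness")

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# 26 triangular mel filters spanning 0 .. fs/2, rows = filters, cols = bins.
mel_filterbank <- function(bin_freqs, n_filters = 26L) {
  fs2 <- max(bin_freqs)
  edges <- mel_to_hz(seq(0, hz_to_mel(fs2), length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, length(bin_freqs))
  for (m in seq_len(n_filters)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- bin_freqs >= lo & bin_freqs <= ce
    dn <- bin_freqs > ce & bin_freqs <= hi
    fb[m, up] <- (bin_freqs[up] - lo) / max(ce - lo, 1e-12)
    fb[m, dn] <- (hi - bin_freqs[dn]) / max(hi - ce, 1e-12)
  }
  fb
}

#' Mel-frequency cepstral coefficients of a clip
#'
#' Frame-wise mel filterbank log-energies (floor 1e-10) followed by the
#' cosine transform `c_n = sum_m E(m) cos(pi * n * (m - 0.5) / M)`,
#' coefficients 1..L (the energy coefficient c0 is excluded), averaged over
#' frames.
#'
#' @param clip an [audio_clip()] or numeric vector at 44100 Hz.
#' @param L number of coefficients (default 13).
#' @param M number of triangular mel filters (default 26).
#' @return Named numeric vector `mfcc_1` .. `mfcc_L`; always finite.
#' @export
mfcc <- function(clip, L = 13L, M = 26L) {
  clip <- as_clip(clip)
  st <- stft_mag(clip$samples, clip$fs)
  fb <- mel_filterbank(st$bin_freqs, M)
  # frames x filters matrix of log filterbank power
  E <- log(pmax(st$mag^2 %*% t(fb), 1e-10))
  dct_basis <- outer(seq_len(M) - 0.5, seq_len(L),
                     function(m, n) cos(pi * n * m / M))
  cc <- colMeans(E %*% dct_basis)
  names(cc) <- paste0("mfcc_", seq_len(L))
  cc
}

#' Spectral centroid of a clip
#'
#' Energy-weighted mean frequency over the clip's STFT, pooling energy across
#' all frames: `sum(f * E) / sum(E)` with `E` the squared magnitudes.
#'
#' @param clip an [audio_clip()] or numeric vector.
#' @return Centroid in Hz; 0 for an all-zero clip.
#' @export
spectral_centroid <- function(clip) {
  clip <- as_clip(clip)
  st <- stft_mag(clip$samples, clip$fs)
  E <- st$mag^2
  tot <- sum(E)
  if (tot <= 0) return(0)
  sum(colSums(E) * st$bin_freqs) / tot
}

#' Spectral flux of a clip
#'
#' For consecutive frame pairs of unit-normalized (L2) magnitude spectra,
#' the summed squared difference, averaged over pairs. Stationary content
#' gives 0.
#'
#' @param clip an [audio_clip()] or numeric vector (>= 2 frames).
#' @return Non-negative scalar.
#' @export
spectral_flux <- function(clip) {
  clip <- as_clip(clip)
  st <- stft_mag(clip$samples, clip$fs)
  if (st$n_frames < 2L) stop_input("need >= 2 frames for spectral flux")
  nrm <- sqrt(rowSums(st$mag^2))
  N <- st$mag / ifelse(nrm > 0, nrm, 1)
  d <- N[-1L, , drop = FALSE] - N[-st$n_frames, , drop = FALSE]
  mean(rowSums(d^2))
}

#' Zero-crossing count of a clip
#'
#' `0.5 * sum |sign(x_m) - sign(x_(m-1))|` with `sign(x) = 1` for `x >= 0`
#' and `-1` otherwise; the total count over the clip, not a rate.
#'
#' @param clip an [audio_clip()] or numeric vector, length >= 2.
#' @return Non-negative integer count.
#' @export
zero_crossings <- function(clip) {
  clip <- as_clip(clip)
  x <- clip$samples
  if (length(x) < 2L) stop_input("need at least 2 samples")
  s <- ifelse(x >= 0, 1, -1)
  sum(abs(diff(s))) / 2
}

#' Root mean square level of a clip
#'
#' @param clip an [audio_clip()] or numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(clip) {
  clip <- as_clip(clip)
  sqrt(mean(clip$samples^2))
}

#' Tempo and pulse clarity of a clip
#'
#' Builds an onset-strength envelope (half-wave-rectified frame-to-frame
#' spectral magnitude increase on a 1024/256 STFT), autocorrelates it, finds
#' the strongest peak within the beat-period search range, refines the lag by
#' parabolic interpolation, and returns `BPM = 60 / T`. Pulse clarity is the
#' autocorrelation peak height normalized by the lag-0 value.
#'
#' @param clip an [audio_clip()] or numeric vector.
#' @param bpm_range search range in beats/min (default `c(60, 180)`).
#' @return List with `bpm`, `bpm_intensity` in `[0, 1]`, and `degenerate`
#'   (TRUE for silent input, where `bpm` is the range midpoint).
#' @export
estimate_bpm <- function(clip, bpm_range = c(60, 180)) {
  clip <- as_clip(clip)
  st <- stft_mag(clip$samples, clip$fs, frame_length = 1024L, hop = 256L)
  # square-root magnitude compression: damps the influence of steady loud
  # partials (whose beating would otherwise imprint on the envelope) while
  # keeping broadband onsets dominant
  M <- sqrt(st$mag)
  d <- M[-1L, , drop = FALSE] - M[-st$n_frames, , drop = FALSE]
  env <- rowSums(pmax(d, 0))
  env_rate <- clip$fs / st$hop
  # light Hann smoothing widens beat peaks so the autocorrelation is not
  # sensitive to fractional beat periods (prevents octave errors)
  k <- 0.5 - 0.5 * cos(2 * pi * (1:5) / 6)
  k <- k / sum(k)
  env <- stats::filter(c(env[2:3], env, env[length(env) - 1:2]), k, sides = 2)
  env <- as.numeric(env[3:(length(env) - 2)])
  env <- env - mean(env)
  if (sum(env^2) <= 1e-20) {
    return(list(bpm = mean(bpm_range), bpm_intensity = 0, degenerate = TRUE))
  }
  m <- length(env)
  # linear autocorrelation via zero-padded circular convolution
  ac <- stats::convolve(c(env, numeric(m)), c(env, numeric(m)),
                        conj = TRUE, type = "circular")[seq_len(m)]
  lag_lo <- max(2L, as.integer(floor(60 / bpm_range[2] * env_rate)))
  lag_hi <- min(m - 1L, as.integer(ceiling(60 / bpm_range[1] * env_rate)))
  if (lag_hi <= lag_lo)
    return(list(bpm = mean(bpm_range), bpm_intensity = 0, degenerate = TRUE))
  lags <- lag_lo:lag_hi
  pk <- lags[which.max(ac[lags + 1L])]
  # subharmonic correction: prefer the half-period if it is nearly as strong
  half <- as.integer(round(pk / 2))
  if (half >= lag_lo && half + 1L <= pk - 1L) {
    hwin <- max(lag_lo, half - 2L):min(lag_hi, half + 2L)
    hpk <- hwin[which.max(ac[hwin + 1L])]
    if (ac[hpk + 1L] >= 0.75 * ac[pk + 1L]) pk <- hpk
  }
  # parabolic refinement around the discrete peak
  y1 <- ac[pk]; y2 <- ac[pk + 1L]; y3 <- ac[pk + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  lag_star <- pk + delta
  bpm <- 60 / (lag_star / env_rate)
  bpm <- max(bpm_range[1], min(bpm_range[2], bpm))
  intensity <- max(0, min(1, y2 / ac[1]))
  list(bpm = bpm, bpm_intensity = intensity, degenerate = FALSE)
}

# Krumhansl-Kessler probe-tone key profiles, C-based.
KK_MAJOR <- c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09, 2.52, 5.19, 2.39, 3.66, 2.29, 2.88)
KK_MINOR <- c(6.33, 2.68, 3.52, 5.38, 2.60, 3.53, 2.54, 4.75, 3.98, 2.69, 3.34, 3.17)

# 12-bin chroma vector (C = bin 1) from an 8192-sample STFT, covering the
# five whole octaves C2..C7. Bin energies are weighted by 1/f (energy per
# log-frequency) so that spectrally flat input yields a flat chroma instead
# of a ramp toward the classes that collect more FFT bins.
chroma_vector <- function(clip) {
  clip <- as_clip(clip)
  st <- stft_mag(clip$samples, clip$fs, frame_length = 8192L, hop = 4096L)
  c2 <- 261.6256 / 4
  keep <- st$bin_freqs >= c2 & st$bin_freqs < c2 * 32
  f <- st$bin_freqs[keep]
  pc <- (round(12 * log2(f / 261.6256)) %% 12) + 1L   # C -> class 1
  energy <- colSums(st$mag[, keep, drop = FALSE]^2) / f
  as.numeric(tapply(energy, factor(pc, levels = 1:12), sum, default = 0))
}

#' Major/minor mode score of a clip
#'
#' Correlates the clip's 12-bin chroma with all 12 rotations of the
#' Krumhansl-Kessler major and minor key profiles; the score is
#' `max(major correlations) - max(minor correlations)`, positive for major
#' tonality. The score is bounded in `[-2, 2]`.
#'
#' @param clip an [audio_clip()] or numeric vector.
#' @return Signed scalar; 0 for silence.
#' @export
estimate_mode <- function(clip) {
  ch <- chroma_vector(clip)
  if (sum(ch) <= 0 || stats::sd(ch) == 0) return(0)
  rot <- function(p, k) p[((seq_len(12) - 1 - k) %% 12) + 1]
  cors <- function(profile) vapply(0:11, function(k) stats::cor(ch, rot(profile, k)),
                                   numeric(1))
  max(cors(KK_MAJOR)) - max(cors(KK_MINOR))
}

# Plomp-Levelt pairwise dissonance (Sethares parameterization).
pl_dissonance <- function(f1, f2, a1, a2) {
  fmin <- pmin(f1, f2); df <- abs(f1 - f2)
  s <- 0.24 / (0.0207 * fmin + 18.96)
  a1 * a2 * (exp(-3.5 * s * df) - exp(-5.75 * s * df))
}

# Spectral peaks of one magnitude frame: local maxima over +/-3 bins, at
# least 5% of the frame maximum, top `max_peaks` by magnitude.
frame_peaks <- function(mag, bin_freqs, max_peaks = 15L) {
  n <- length(mag)
  thr <- 0.05 * max(mag)
  if (thr <= 0) return(NULL)
  cand <- which(mag >= thr)
  cand <- cand[cand > 3L & cand < n - 3L]
  if (!length(cand)) return(NULL)
  is_max <- vapply(cand, function(i) mag[i] == max(mag[(i - 3L):(i + 3L)]),
                   logical(1))
  cand <- cand[is_max]
  if (!length(cand)) return(NULL)
  if (length(cand) > max_peaks) cand <- cand[order(mag[cand], decreasing = TRUE)[seq_len(max_peaks)]]
  list(freq = bin_freqs[cand], amp = mag[cand])
}

#' Sensory roughness of a clip
#'
#' Detects spectral peaks per frame (16384-sample frames for fine frequency
#' resolution) and sums pairwise Plomp-Levelt dissonance contributions over
#' peak pairs, with amplitudes normalized by the frame maximum; the clip
#' value is the mean over frames. Beating partials a few tens of Hz apart
#' maximize the curve; a lone pure tone contributes nothing.
#'
#' @param clip an [audio_clip()] or numeric vector.
#' @return Non-negative scalar; 0 for silence.
#' @export
roughness <- function(clip) {
  clip <- as_clip(clip)
  st <- stft_mag(clip$samples, clip$fs, frame_length = 16384L, hop = 8192L)
  vals <- vapply(seq_len(st$n_frames), function(i) {
    mag <- st$mag[i, ]
    mx <- max(mag)
    if (mx <= 0) return(0)
    pk <- frame_peaks(mag, st$bin_freqs)
    if (is.null(pk) || length(pk$freq) < 2L) return(0)
    a <- pk$amp / mx
    idx <- utils::combn(length(pk$freq), 2L)
    sum(pl_dissonance(pk$freq[idx[1, ]], pk$freq[idx[2, ]],
                      a[idx[1, ]], a[idx[2, ]]))
  }, numeric(1))
  mean(vals)
}

#' The 21-dimensional music feature vector of a clip
#'
#' Computes all nine feature families — 13 MFCCs, spectral centroid, spectral
#' flux, zero crossings, RMS, BPM, BPM intensity (pulse clarity), mode score,
#' and roughness — in a fixed documented order.
#'
#' @param clip an [audio_clip()] or numeric vector at 44100 Hz.
#' @return Named numeric vector of length 21 (see `MUSIC_FEATURE_NAMES`).
#' @export
extract_music_features <- function(clip) {
  clip <- as_clip(clip)
  bpm <- estimate_bpm(clip)
  v <- c(mfcc(clip),
         spectral_centroid = spectral_centroid(clip),
         spectral_flux = spectral_flux(clip),
         zero_crossings = zero_crossings(clip),
         rms = rms(clip),
         bpm = bpm$bpm,
         bpm_intensity = bpm$bpm_intensity,
         mode = estimate_mode(clip),
         roughness = roughness(clip))
  stopifnot(identical(names(v), MUSIC_FEATURE_NAMES))
  v
}

#' Feature table for a set of audio clips
#'
#' @param clips list of [audio_clip()] objects.
#' @param labels optional class label per clip.
#' @return Data frame: `source_id`, `clip_index`, the 21 feature columns, and
#'   `label` when labels are given.
#' @export
music_feature_table <- function(clips, labels = NULL) {
  if (!length(clips)) stop_input("'clips' is empty")
  if (!is.null(labels) && length(labels) != length(clips))
    stop_input("%d labels for %d clips", length(labels), length(clips))
  feats <- t(vapply(clips, extract_music_features, numeric(21)))
  df <- data.frame(
    source_id = vapply(clips, function(cl) as.character(cl$source_id), character(1)),
    clip_index = vapply(clips, function(cl) cl$clip_index, integer(1)),
    feats, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  df
}
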