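# Band-power EEG features: db4 sub-band decomposition into the classical
# delta/theta/alpha/beta/gamma bands, Welch periodogram per band, and the
# average log-PSD (dB) per channel per band.

BAND_NAMES <- c("delta", "theta", "alpha", "beta", "gamma")
FEATURE_BANDS <- c("theta", "alpha", "beta", "gamma")

#' Dyadic sub-band scheme of the wavelet decomposition
#'
#' For a 5-band scheme the db4 filter bank is cascaded 4 times, giving
#' coefficient groups A4, D4, D3, D2, D1 that cover
#' `[1, fs/32]`, `[fs/32, fs/16]`, `[fs/16, fs/8]`, `[fs/8, fs/4]`,
#' `[fs/4, fs/2]` — at fs = 128 Hz the classical delta (1-4), theta (4-8),
#' alpha (8-16), beta (16-32) and gamma (32-64 Hz) EEG bands. The
#' approximation's nominal lower edge is quoted as 1 Hz by convention.
#'
#' @param fs sampling rate in Hz.
#' @param levels number of sub-bands (default 5, the only named scheme).
#' @return A `"subband_scheme"` data frame with columns `band`,
#'   `level_label`, `f_low`, `f_high`.
#' @export
subband_ranges <- function(fs, levels = 5) {
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  check_scalar(levels, "levels", lower = 1)
  levels <- as.integer(levels)
  if (fs / 2^levels < 1)
    stop_input("fs = %g cannot support %d dyadic bands above 1 Hz", fs, levels)
  n_det <- levels - 1L
  f_high <- fs / 2^(levels:1)
  f_low <- c(1, f_high[-levels])
  labels <- c(paste0("A", n_det), paste0("D", rev(seq_len(n_det))))
  band <- if (levels == 5L) BAND_NAMES else paste0("band", seq_len(levels))
  structure(data.frame(band = band, level_label = labels,
                       f_low = f_low, f_high = f_high,
                       stringsAsFactors = FALSE),
            class = c("subband_scheme", "data.frame"), fs = fs)
}

#' Decompose a signal into wavelet sub-band time series
#'
#' Runs a 4-level db4 decomposition and reconstructs each coefficient group
#' (A4, D4, D3, D2, D1) in isolation, yielding five band-limited signals of
#' the input length whose sum reproduces the input exactly (linearity of the
#' inverse transform).
#'
#' @param signal numeric vector; must admit a 4-level db4 decomposition
#'   (length >= 112).
#' @param fs sampling rate in Hz (names the bands via [subband_ranges()]).
#' @return Named list of five numeric vectors (`delta` ... `gamma`), with the
#'   scheme attached as attribute `"scheme"`.
#' @export
wavelet_band_decompose <- function(signal, fs) {
  check_numeric_vector(signal, "signal", min_len = 2L)
  n_levels <- 4L
  if (dwt_max_level(length(signal)) < n_levels)
    stop_input("signal length %d too short for a %d-level decomposition",
               length(signal), n_levels)
  scheme <- subband_ranges(fs, 5)
  wd <- wavedec(signal, n_levels)
  zero <- function(w) { w$approx[] <- 0; w$details <- lapply(w$details, function(d) d * 0); w }
  bands <- vector("list", 5L)
  w0 <- zero(wd)
  wa <- w0; wa$approx <- wd$approx
  bands[[1]] <- waverec(wa)                       # A4 -> delta
  for (k in seq_len(n_levels)) {                  # details[[k]]: k=1 deepest (D4)
    wk <- w0; wk$details[[k]] <- wd$details[[k]]
    bands[[k + 1L]] <- waverec(wk)                # D4, D3, D2, D1
  }
  names(bands) <- scheme$band
  attr(bands, "scheme") <- scheme
  bands
}

#' Welch averaged-periodogram PSD estimate
#'
#' Splits the signal into `n_segments` Hamming-windowed segments at the given
#' overlap (default 8 segments at 50%), averaging one-sided periodograms with
#' density scaling. The segment length is the largest even value fitting the
#' segmentation; trailing samples are clipped.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param n_segments number of segments (default 8).
#' @param overlap fractional overlap between consecutive segments (default 0.5).
#' @return A `"psd_estimate"` list: `freqs` (Hz), `Pxx` (power/Hz, >= 0),
#'   `P` (number of PSD points), `params`.
#' @export
welch_psd <- function(signal, fs, n_segments = 8, overlap = 0.5) {
  check_numeric_vector(signal, "signal", min_len = 2L)
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  check_scalar(n_segments, "n_segments", lower = 1)
  if (overlap < 0 || overlap >= 1) stop_input("'overlap' must be in [0, 1)")
  N <- length(signal)
  # L + (S-1) * L * (1 - overlap) <= N, L even
  L <- floor(N / (1 + (n_segments - 1) * (1 - overlap)))
  L <- as.integer(2 * (L %/% 2))
  if (L < 4L) stop_input("signal too short (%d samples) for %g segments", N, n_segments)
  hop <- as.integer(round(L * (1 - overlap)))
  starts <- as.integer(seq(1L, by = hop, length.out = n_segments))
  starts <- starts[starts + L - 1L <= N]
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
  scale <- 1 / (fs * sum(w^2))
  nb <- L %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- signal[s:(s + L - 1L)] * w
    sp <- Mod(stats::fft(seg))^2 * scale
    half <- sp[seq_len(nb)]
    half[2:(nb - 1L)] <- 2 * half[2:(nb - 1L)]
    acc <- acc + half
  }
  Pxx <- acc / length(starts)
  structure(list(freqs = (0:(nb - 1L)) * fs / L, Pxx = Pxx, P = nb,
                 params = list(n_segments = length(starts), window = "hamming",
                               overlap_fraction = overlap, segment_length = L)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d points, %g-%g Hz, %d x %s segments (overlap %g)\n",
              x$P, min(x$freqs), max(x$freqs), x$params$n_segments,
              x$params$window, x$params$overlap_fraction))
  invisible(x)
}

#' Average log power spectral density in dB
#'
#' `AvgPSD = mean(10 * log10(Pxx))` over all PSD points, with `Pxx` floored
#' at 1e-12 so silent bands stay finite.
#'
#' @param psd a [welch_psd()] result (or any list with a `Pxx` field).
#' @return Scalar, dB.
#' @export
avg_log_psd <- function(psd) {
  if (!is.list(psd) || is.null(psd$Pxx)) stop_input("'psd' must be a psd_estimate")
  Pxx <- pmax(psd$Pxx, 1e-12)
  sum(10 * log10(Pxx)) / length(Pxx)
}

#' Band-power feature vector of an EEG recording
#'
#' Per channel: wavelet denoising ([denoise_signal()]), 4.0-45.0 Hz zero-phase
#' band-pass ([bandpass_4_45()]), db4 sub-band decomposition
#' ([wavelet_band_decompose()]), then per selected band a Welch PSD whose
#' average log value ([avg_log_psd()]) is the feature. The delta band is
#' discarded by default (sleep-related; removed by the band-pass anyway).
#'
#' @param rec an [eeg_recording()].
#' @param bands band subset, default `c("theta", "alpha", "beta", "gamma")`.
#' @param denoise logical; apply the wavelet denoiser first (default TRUE).
#' @return Named numeric vector of length `n_channels * length(bands)`,
#'   ordered channel-major, band-minor, names `<channel>_<band>`, units dB.
#' @export
extract_eeg_features <- function(rec, bands = FEATURE_BANDS, denoise = TRUE) {
  if (!inherits(rec, "eeg_recording")) stop_input("'rec' must be an eeg_recording")
  bad <- setdiff(bands, BAND_NAMES)
  if (length(bad)) stop_input("unknown band name(s): %s", paste(bad, collapse = ", "))
  out <- numeric(0)
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    if (denoise) x <- denoise_signal(x, rec$fs)
    x <- bandpass_4_45(x, rec$fs)
    dec <- wavelet_band_decompose(x, rec$fs)
    v <- vapply(bands, function(b) avg_log_psd(welch_psd(dec[[b]], rec$fs)),
                numeric(1))
    names(v) <- paste(rec$channel_names[ch], bands, sep = "_")
    out <- c(out, v)
  }
  out
}

#' Feature table for a set of EEG recordings
#'
#' @param recordings list of [eeg_recording()] objects sharing channel layout.
#' @param labels class label per recording (factor or character), optional.
#' @param bands band subset as in [extract_eeg_features()].
#' @param denoise passed to [extract_eeg_features()].
#' @return Data frame: `trial_id`, one `<channel>_<band>` column per feature,
#'   and `label` when labels are given.
#' @export
eeg_feature_table <- function(recordings, labels = NULL, bands = FEATURE_BANDS,
                              denoise = TRUE) {
  if (!length(recordings)) stop_input("'recordings' is empty")
  if (!is.null(labels) && length(labels) != length(recordings))
    stop_input("%d labels for %d recordings", length(labels), length(recordings))
  feats <- t(vapply(recordings, extract_eeg_features,
                    numeric(nrow(recordings[[1]]$samples) * length(bands)),
                    bands = bands, denoise = denoise))
  ids <- vapply(seq_along(recordings), function(i) {
    id <- recordings[[i]]$trial_id
    if (is.na(id)) sprintf("trial%03d", i) else as.character(id)
  }, character(1))
  df <- data.frame(trial_id = ids, feats, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  df
}
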