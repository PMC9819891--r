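# Wavelet denoising of raw EEG: db4 decomposition, a minimax ("extremum")
# threshold estimated from the finest detail coefficients, hard thresholding
# of all detail levels, and exact reconstruction. White-Gaussian noise is the
# target; muscle and eye-blink artifacts are out of scope.

#' Robust noise level from wavelet detail coefficients
#'
#' Estimates the noise standard-deviation coefficient as
#' `median(|w|) / 0.6745`, the classical median-absolute-deviation rule for
#' Gaussian noise applied to detail coefficients. The absolute value is taken
#' before the median: detail coefficients are zero-mean, so a signed median
#' would be degenerate.
#'
#' @param detail_coeffs numeric vector of wavelet detail coefficients
#'   (conventionally the finest level).
#' @return Non-negative noise coefficient estimate.
#' @export
estimate_noise_sigma <- function(detail_coeffs) {
  check_numeric_vector(detail_coeffs, "detail_coeffs")
  stats::median(abs(detail_coeffs)) / 0.6745
}

#' Minimax (extremum) wavelet threshold
#'
#' The threshold-selection rule `lambda = sigma * (0.3936 + 0.1829 * log2(E))`
#' for signals longer than 32 samples, and `lambda = 0` otherwise, where `E`
#' is the signal length in samples and `sigma` the noise coefficient from
#' [estimate_noise_sigma()]. Short signals are passed through untouched.
#'
#' @param E signal length in samples (positive).
#' @param sigma non-negative noise coefficient.
#' @return Non-negative threshold.
#' @export
minimax_threshold <- function(E, sigma) {
  check_scalar(E, "E", lower = 0, strict = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  if (E <= 32) return(0)
  sigma * (0.3936 + 0.1829 * (log(E) / log(2)))
}

#' Hard thresholding of wavelet coefficients
#'
#' Keeps each coefficient verbatim when `|w| >= lambda` (inclusive) and zeroes
#' it otherwise. Idempotent; never increases any coefficient magnitude.
#'
#' @param coeffs numeric coefficient vector.
#' @param lambda non-negative threshold.
#' @return Vector of the same length.
#' @export
hard_threshold <- function(coeffs, lambda) {
  check_numeric_vector(coeffs, "coeffs", min_len = 0L)
  check_scalar(lambda, "lambda", lower = 0)
  ifelse(abs(coeffs) >= lambda, coeffs, 0)
}

#' Denoising configuration
#'
#' @param wavelet_name wavelet family; only `"db4"` is supported.
#' @param threshold_rule threshold selection rule; only `"minimax_extremum"`.
#' @param level decomposition depth: `"auto-max"` (default) uses the maximum
#'   admissible level for the signal length, or a positive integer.
#' @return A `"denoise_config"` list.
#' @export
denoise_config <- function(wavelet_name = "db4",
                           threshold_rule = "minimax_extremum",
                           level = "auto-max") {
  wavelet_name <- match.arg(wavelet_name, "db4")
  threshold_rule <- match.arg(threshold_rule, "minimax_extremum")
  if (!identical(level, "auto-max")) {
    check_scalar(level, "level", lower = 1)
    level <- as.integer(level)
  }
  structure(list(wavelet_name = wavelet_name, threshold_rule = threshold_rule,
                 level = level),
            class = "denoise_config")
}

#' Wavelet denoising of a single signal
#'
#' Decomposes with db4 to the configured level, estimates the noise
#' coefficient from the finest (level-1) detail coefficients, computes one
#' global minimax threshold from the full signal length, hard-thresholds all
#' detail levels (the approximation is left untouched), and reconstructs.
#'
#' @param signal numeric vector, length >= 2.
#' @param fs sampling rate in Hz (recorded for provenance; the threshold rule
#'   itself is sample-based).
#' @param config a [denoise_config()].
#' @param lambda optional explicit threshold overriding the estimated one
#'   (e.g. 0 to verify perfect reconstruction).
#' @return Denoised numeric vector, same length as `signal`.
#' @export
denoise_signal <- function(signal, fs = NULL, config = denoise_config(),
                           lambda = NULL) {
  check_numeric_vector(signal, "signal", min_len = 2L)
  if (!inherits(config, "denoise_config")) stop_input("'config' must be a denoise_config")
  n <- length(signal)
  max_lvl <- dwt_max_level(n)
  if (max_lvl < 1L) return(as.numeric(signal))  # too short to decompose: E <= 32 anyway
  level <- if (identical(config$level, "auto-max")) max_lvl else config$level
  if (level > max_lvl)
    stop_input("level %d exceeds maximum admissible level %d for length %d",
               level, max_lvl, n)
  wd <- wavedec(signal, level)
  if (is.null(lambda)) {
    sigma <- estimate_noise_sigma(wd$details[[wd$level]])  # finest level
    lambda <- minimax_threshold(n, sigma)
  } else {
    check_scalar(lambda, "lambda", lower = 0)
  }
  wd$details <- lapply(wd$details, hard_threshold, lambda = lambda)
  waverec(wd)
}

#' Zero-phase 4.0-45.0 Hz band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), i.e. zero phase and squared magnitude response.
#' Retains the theta-gamma range used for band-power features and discards
#' the delta band and mains-adjacent content.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz; must exceed 90 so that 45 Hz lies below
#'   Nyquist.
#' @return Filtered vector, same length.
#' @export
bandpass_4_45 <- function(signal, fs) {
  check_numeric_vector(signal, "signal", min_len = 2L)
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  if (fs <= 90)
    stop_input("fs must be > 90 Hz for a 4-45 Hz band-pass (got %g)", fs)
  bf <- signal::butter(4, c(4, 45) / (fs / 2), type = "pass")
  signal::filtfilt(bf, signal)
}
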