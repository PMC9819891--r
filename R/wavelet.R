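# Daubechies-4 (db4, 8-tap) discrete wavelet transform with symmetric
# (half-point) boundary extension and exact inversion. Filter coefficients
# are the standard orthonormal db4 bank; dec_hi/rec_* follow the usual
# quadrature-mirror relations.

DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- rev(DB4_DEC_LO)
DB4_REC_HI <- rev(DB4_DEC_HI)
DB4_LEN <- 8L

# Full (open) convolution; stats::convolve is FFT-based and fast.
conv_full <- function(x, f) {
  stats::convolve(x, rev(f), type = "open")
}

sym_extend <- function(x, p) {
  n <- length(x)
  if (p > n) stop_input("signal too short (%d) for boundary extension %d", n, p)
  c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1L):n]))
}

#' Maximum admissible db4 decomposition level
#'
#' The deepest level at which every coefficient vector still holds at least
#' one sample unaffected purely by boundary extension, following the usual
#' `floor(log2(n / (filter_length - 1)))` convention.
#'
#' @param n signal length in samples.
#' @return Integer level (possibly 0 for very short signals).
#' @export
dwt_max_level <- function(n) {
  check_scalar(n, "n", lower = 1)
  if (n < DB4_LEN - 1L) return(0L)
  as.integer(floor(log2(n / (DB4_LEN - 1L))))
}

# One analysis step: returns approximation and detail coefficients,
# each of length floor((n + 7) / 2).
dwt_step <- function(x) {
  n <- length(x)
  ext <- sym_extend(x, DB4_LEN - 1L)
  idx <- seq.int(DB4_LEN + 1L, by = 2L, length.out = (n + DB4_LEN - 1L) %/% 2L)
  list(a = conv_full(ext, DB4_DEC_LO)[idx],
       d = conv_full(ext, DB4_DEC_HI)[idx])
}

# One synthesis step; n_out is the length of the signal being restored.
idwt_step <- function(a, d, n_out) {
  la <- length(a)
  up <- function(cf) { u <- numeric(2L * la); u[seq(1L, 2L * la, 2L)] <- cf; u }
  y <- conv_full(up(a), DB4_REC_LO) + conv_full(up(d), DB4_REC_HI)
  full_len <- 2L * la - DB4_LEN + 2L
  y <- y[(DB4_LEN - 1L):(DB4_LEN - 2L + full_len)]
  y[seq_len(n_out)]
}

#' Multi-level db4 wavelet decomposition
#'
#' Cascades the analysis filter bank `level` times with symmetric boundary
#' extension. The result reconstructs exactly (to floating-point precision)
#' via [waverec()].
#'
#' @param x numeric signal.
#' @param level number of decomposition levels (>= 1); defaults to
#'   [dwt_max_level()] of the signal length.
#' @return An object of class `"wavedec"`: a list with `approx` (deepest
#'   approximation coefficients), `details` (list, deepest level first),
#'   `level`, and `lengths` (per-level input lengths used for inversion).
#' @seealso [waverec()], [denoise_signal()]
#' @export
wavedec <- function(x, level = NULL) {
  check_numeric_vector(x, "x", min_len = 2L)
  max_lvl <- dwt_max_level(length(x))
  if (is.null(level)) level <- max_lvl
  check_scalar(level, "level", lower = 1)
  level <- as.integer(level)
  if (level > max_lvl)
    stop_input("level %d exceeds maximum admissible level %d for length %d",
               level, max_lvl, length(x))
  details <- vector("list", level)
  lengths <- integer(level)
  a <- as.numeric(x)
  for (k in seq_len(level)) {
    lengths[k] <- length(a)
    s <- dwt_step(a)
    details[[level - k + 1L]] <- s$d
    a <- s$a
  }
  structure(list(approx = a, details = details, level = level,
                 lengths = rev(lengths)),
            class = "wavedec")
}

#' Reconstruct a signal from a db4 wavelet decomposition
#'
#' @param wd a `"wavedec"` object from [wavedec()].
#' @return Numeric vector of the original signal length.
#' @export
waverec <- function(wd) {
  if (!inherits(wd, "wavedec")) stop_input("'wd' must be a wavedec object")
  a <- wd$approx
  for (k in seq_len(wd$level)) {
    a <- idwt_step(a, wd$details[[k]], wd$lengths[k])
  }
  a
}
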