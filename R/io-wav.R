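# Minimal RIFF/WAVE reader and writer: PCM 16/24/32-bit and IEEE float32,
# the formats produced by common editors. Samples are exchanged as numeric
# vectors in [-1, 1] using the conventional two's-complement scaling
# (x / 2^(bits-1)); float data is passed through untouched.

#' Read a WAV file
#'
#' @param path file path.
#' @param strict_fs if non-NULL, error unless the file's sampling rate equals
#'   this value (the music pipeline requires 44100 Hz; no resampling is done).
#' @return List with `samples` (numeric matrix, channels x frames, in
#'   `[-1, 1]`), `fs`, `bits`, and `format` (`"pcm"` or `"float"`).
#' @export
read_wav <- function(path, strict_fs = NULL) {
  if (!file.exists(path)) stop_input("WAV file not found: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop_input("%s: not a RIFF file (offset 0)", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop_input("%s: not a WAVE file (offset 8)", path)
  fmt <- NULL; data_raw <- NULL; offset <- 12
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) stop_input("%s: truncated chunk header at byte %d", path, offset)
    if (id == "fmt ") {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(body[3:4]) * c(1, 256)),
        fs = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz)
        stop_input("%s: data chunk truncated at byte %d (expected %d bytes, got %d)",
                   path, offset + 8, sz, length(data_raw))
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    offset <- offset + 8 + sz + sz %% 2
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop_input("%s: missing fmt chunk", path)
  if (is.null(data_raw)) stop_input("%s: missing data chunk", path)
  if (!is.null(strict_fs) && fmt$fs != strict_fs)
    stop_input("%s: sampling rate %d Hz, expected %d Hz (resampling refused)",
               path, fmt$fs, strict_fs)
  nch <- fmt$n_channels
  if (fmt$audio_format == 3L) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4,
                 endian = "little")
    format <- "float"
  } else if (fmt$audio_format == 1L) {
    bytes <- fmt$bits %/% 8L
    n <- length(data_raw) %/% bytes
    if (fmt$bits == 16) {
      x <- readBin(data_raw, "integer", n, size = 2, signed = TRUE,
                   endian = "little") / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3)
      v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else if (fmt$bits == 32) {
      x <- readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648
    } else stop_input("%s: unsupported PCM bit depth %d", path, fmt$bits)
    format <- "pcm"
  } else stop_input("%s: unsupported audio format tag %d", path, fmt$audio_format)
  samples <- matrix(x, nrow = nch)  # interleaved -> channels x frames
  list(samples = samples, fs = fmt$fs, bits = fmt$bits, format = format)
}

#' Write a WAV file
#'
#' @param samples numeric vector (mono) or channels x frames matrix in
#'   `[-1, 1]`.
#' @param path destination path.
#' @param fs sampling rate in Hz.
#' @param format `"float"` (IEEE float32, lossless for generated material,
#'   the default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs = AUDIO_FS, format = c("float", "pcm16")) {
  format <- match.arg(format)
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  nch <- nrow(samples); nfr <- ncol(samples)
  x <- as.numeric(samples)  # column-major = interleaved frames
  bytes <- if (format == "float") 4L else 2L
  data_size <- nfr * nch * bytes
  con <- file(path, "wb"); on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(if (format == "float") 3 else 1); w16(nch); w32(fs)
  w32(fs * nch * bytes); w16(nch * bytes); w16(bytes * 8L)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (format == "float") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Load an audio file for the music pipeline
#'
#' Reads a WAV file, enforcing the 44100 Hz contract, and returns the stereo
#' pair (or mono channel) ready for [merge_stereo()].
#'
#' @param path WAV file path.
#' @param strict enforce fs == 44100 (default TRUE).
#' @return List with `left`, `right` (NULL for mono) and `fs`.
#' @export
load_audio <- function(path, strict = TRUE) {
  w <- read_wav(path, strict_fs = if (strict) AUDIO_FS else NULL)
  list(left = w$samples[1, ],
       right = if (nrow(w$samples) > 1) w$samples[2, ] else NULL,
       fs = w$fs)
}
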