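# Audio clip container, stereo merge, fixed-length segmentation, and the
# short-time Fourier transform shared by the spectral features.

AUDIO_FS <- 44100L
CLIP_SECONDS <- 15

#' Construct an audio clip
#'
#' @param samples numeric vector in `[-1, 1]`, mono.
#' @param fs sampling rate in Hz (default 44100).
#' @param source_id identifier of the source track.
#' @param clip_index 0-based offset of the clip within its source.
#' @return An object of class `"audio_clip"`.
#' @export
audio_clip <- function(samples, fs = AUDIO_FS, source_id = NA_character_,
                       clip_index = 0L) {
  check_numeric_vector(samples, "samples")
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  if (max(abs(samples)) > 1 + 1e-9)
    stop_input("samples exceed [-1, 1] (max |x| = %g)", max(abs(samples)))
  structure(list(samples = as.numeric(samples), fs = fs,
                 source_id = source_id, clip_index = as.integer(clip_index)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.2f s @ %d Hz, source %s, index %d\n",
              length(x$samples) / x$fs, x$fs, x$source_id, x$clip_index))
  invisible(x)
}

#' Merge stereo channels to mono
#'
#' Element-wise mean of left and right, retaining all audio information in a
#' single channel.
#'
#' @param left,right numeric vectors of equal length.
#' @return Mono numeric vector.
#' @export
merge_stereo <- function(left, right) {
  check_numeric_vector(left, "left")
  check_numeric_vector(right, "right")
  if (length(left) != length(right))
    stop_input("channel lengths differ: %d vs %d", length(left), length(right))
  (left + right) / 2
}

#' Segment a mono signal into fixed-length clips
#'
#' Cuts `trunc(length / fs / clip_seconds)` consecutive non-overlapping clips
#' from the start of the signal; any remainder is discarded.
#'
#' @param mono numeric vector.
#' @param fs sampling rate in Hz.
#' @param clip_seconds clip length in seconds (default 15).
#' @param source_id identifier passed to each [audio_clip()].
#' @return List of [audio_clip()] objects (possibly empty).
#' @export
segment_clips <- function(mono, fs = AUDIO_FS, clip_seconds = CLIP_SECONDS,
                          source_id = NA_character_) {
  check_numeric_vector(mono, "mono", min_len = 0L)
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  n_clip <- as.integer(fs * clip_seconds)
  sn <- trunc(length(mono) / fs / clip_seconds)
  if (sn < 1) return(list())
  lapply(seq_len(sn) - 1L, function(i) {
    audio_clip(mono[(i * n_clip + 1L):((i + 1L) * n_clip)], fs = fs,
               source_id = source_id, clip_index = i)
  })
}

# Short-time Fourier transform magnitudes. Returns frames x bins matrix of
# magnitudes for the one-sided spectrum, with bin frequencies in Hz.
stft_mag <- function(x, fs, frame_length = 2048L, hop = 1024L,
                     window = c("hann", "hamming")) {
  window <- match.arg(window)
  n <- length(x)
  if (n < frame_length) stop_input("signal (%d) shorter than one frame (%d)", n, frame_length)
  starts <- seq.int(1L, n - frame_length + 1L, by = hop)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(frame_length - 1)) / (frame_length - 1))
       else 0.54 - 0.46 * cos(2 * pi * (0:(frame_length - 1)) / (frame_length - 1))
  frames <- vapply(starts, function(s) x[s:(s + frame_length - 1L)] * w,
                   numeric(frame_length))
  nb <- frame_length %/% 2L + 1L
  mag <- t(Mod(stats::mvfft(frames))[seq_len(nb), , drop = FALSE])
  list(mag = mag, bin_freqs = (0:(nb - 1L)) * fs / frame_length,
       frame_length = frame_length, hop = hop, n_frames = length(starts))
}

as_clip <- function(clip) {
  if (inherits(clip, "audio_clip")) return(clip)
  if (is.numeric(clip)) return(audio_clip(clip))
  stop_input("expected an audio_clip or numeric vector")
}
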