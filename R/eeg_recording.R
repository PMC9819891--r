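# EEG container: a channels x samples matrix with its sampling rate and
# 10-20-system channel names.

#' Construct an EEG recording
#'
#' @param samples numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names unique channel labels (10-20 system), one per row.
#' @param trial_id,subject_id opaque identifiers.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(samples, fs, channel_names = NULL,
                          trial_id = NA_character_, subject_id = NA_character_) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_input("'samples' must be a numeric matrix (channels x samples)")
  if (ncol(samples) < 1L) stop_input("'samples' must have at least one sample")
  if (anyNA(samples)) stop_input("'samples' contains NA")
  check_scalar(fs, "fs", lower = 0, strict = TRUE)
  fs <- as.numeric(fs)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples))
    stop_input("%d channel names for %d rows", length(channel_names), nrow(samples))
  dup <- unique(channel_names[duplicated(channel_names)])
  if (length(dup))
    stop_input("duplicate channel names: %s", paste(dup, collapse = ", "))
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 trial_id = trial_id, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  if (!is.na(x$trial_id)) cat("  trial:", x$trial_id, "\n")
  cat("  channels:", paste(utils::head(x$channel_names, 8), collapse = " "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Channel names of the 32-electrode DEAP-style 10-20 montage
#'
#' @return Character vector of 32 labels.
#' @export
montage_32 <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

#' Read an EEG recording from CSV plus JSON sidecar
#'
#' The CSV holds one channel per row: first column the channel name, the
#' remaining columns samples. The sidecar (default `<path>.json`) must
#' provide `fs` in Hz and may provide `trial_id` / `subject_id`.
#'
#' @param path CSV file path.
#' @param sidecar JSON sidecar path.
#' @return An [eeg_recording()].
#' @export
load_eeg <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop_input("EEG file not found: %s", path)
  if (!file.exists(sidecar)) stop_input("sidecar not found: %s", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs)) stop_input("sidecar %s lacks required field 'fs'", sidecar)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_input("%s: need a name column plus samples", path)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop_input("%s: ragged or non-numeric sample rows", path)
  eeg_recording(mat, fs = meta$fs, channel_names = raw[[1]],
                trial_id = if (is.null(meta$trial_id)) NA_character_ else meta$trial_id,
                subject_id = if (is.null(meta$subject_id)) NA_character_ else meta$subject_id)
}

#' Write an EEG recording to CSV plus JSON sidecar
#'
#' @param rec an [eeg_recording()].
#' @param path CSV destination; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stop_input("'rec' must be an eeg_recording")
  df <- data.frame(channel = rec$channel_names,
                   rec$samples, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     qmethod = "double")
  jsonlite::write_json(list(fs = rec$fs, trial_id = rec$trial_id,
                            subject_id = rec$subject_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
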