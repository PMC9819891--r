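# Feature-table CSV round-trip and run manifests. CSV dialect: comma
# separator, '.' decimal, UTF-8, '\n' line endings, values at full double
# precision.

#' Write a feature table to CSV
#'
#' @param table data frame from [eeg_feature_table()] or
#'   [music_feature_table()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table)) stop_input("'table' must be a data frame")
  tbl <- table
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], function(v) sprintf("%.15g", v))
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Columns may appear in any order; they are returned in the canonical order
#' given by `expected` when supplied.
#'
#' @param path CSV path.
#' @param expected optional character vector of required column names.
#' @return Data frame.
#' @export
read_feature_table <- function(path, expected = NULL) {
  if (!file.exists(path)) stop_input("feature table not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(expected)) {
    missing <- setdiff(expected, colnames(df))
    extra <- setdiff(colnames(df), expected)
    if (length(missing) || length(extra))
      stop_input("header mismatch in %s: missing [%s], extra [%s]", path,
                 paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    df <- df[, expected, drop = FALSE]
  }
  df
}

# Manifest describing a run: configuration, seed and package version, enough
# to reproduce the outputs.
write_manifest <- function(path, config = list(), seed = NA_integer_) {
  jsonlite::write_json(
    list(package = "emomap",
         version = as.character(utils::packageVersion("emomap")),
         seed = seed, config = config,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
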