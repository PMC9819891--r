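# Valence-arousal emotion mapping: the 20-emotion vocabulary with
# approximate anchor coordinates, quadrant labels, and music-type-conditioned
# emotion-transition tables.

EMOTIONS_20 <- c("intimacy", "surprise", "tiredness", "anxiety", "concentration",
                 "pain", "relaxation", "confidence", "disgust", "insecurity",
                 "fear", "despair", "hope", "gratitude", "anger", "passion",
                 "sadness", "mania", "joy", "trust")

QUADRANTS <- c("HVHA", "HVLA", "LVHA", "LVLA")

#' Default valence-arousal anchors for the 20-emotion vocabulary
#'
#' Coordinates on the 1-9 self-rating scale. The published emotion map gives
#' quadrant placements but no numeric coordinates, so these anchors are
#' approximate, ship as an editable CSV
#' (`system.file("extdata", "emotion_anchors.csv", package = "emomap")`), and
#' can be replaced wholesale; they are a configuration default, not ground
#' truth.
#'
#' @param file optional CSV with columns `name`, `valence`, `arousal`
#'   overriding the packaged defaults.
#' @return Data frame with columns `name`, `valence`, `arousal` (20 rows for
#'   the default set).
#' @export
default_emotion_anchors <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "emotion_anchors.csv", package = "emomap")
  a <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "valence", "arousal")
  if (!all(need %in% colnames(a)))
    stop_input("anchor file must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(a$name)) stop_input("duplicate anchor names")
  if (any(a$valence < 1 | a$valence > 9 | a$arousal < 1 | a$arousal > 9))
    stop_input("anchor coordinates must lie in [1, 9]")
  a[, need]
}

check_rating <- function(valence, arousal) {
  if (any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9))
    stop_input("valence/arousal ratings must lie in [1, 9]")
}

#' Annotate a valence-arousal rating with its nearest emotion
#'
#' Assigns the anchor with the smallest Euclidean distance in the
#' (valence, arousal) plane; exact ties resolve to the lexicographically
#' first emotion name. Vectorized over ratings.
#'
#' @param valence,arousal numeric ratings in `[1, 9]` (equal length).
#' @param anchors anchor table from [default_emotion_anchors()].
#' @return Character vector of emotion names.
#' @export
annotate_emotion <- function(valence, arousal, anchors = default_emotion_anchors()) {
  check_rating(valence, arousal)
  if (length(valence) != length(arousal))
    stop_input("valence and arousal lengths differ")
  ord <- order(anchors$name)
  anchors <- anchors[ord, ]
  vapply(seq_along(valence), function(i) {
    d2 <- (anchors$valence - valence[i])^2 + (anchors$arousal - arousal[i])^2
    anchors$name[which.min(d2)]  # ties: first = lexicographically smallest
  }, character(1))
}

#' Valence-arousal quadrant of a rating
#'
#' `HV`/`LV` by valence and `HA`/`LA` by arousal against the threshold;
#' boundary values are assigned to the High side. Vectorized.
#'
#' @param valence,arousal numeric ratings in `[1, 9]`.
#' @param threshold scale midpoint (default 5).
#' @return Character vector of `"HVHA"`, `"HVLA"`, `"LVHA"`, `"LVLA"`.
#' @export
quadrant <- function(valence, arousal, threshold = 5) {
  check_rating(valence, arousal)
  paste0(ifelse(valence >= threshold, "HV", "LV"),
         ifelse(arousal >= threshold, "HA", "LA"))
}

#' Music-conditioned emotion transition probabilities
#'
#' Estimates `P(after | before, music_type)` as the empirical conditional
#' frequency over before/music/after records. At `"quadrant"` granularity,
#' emotion labels are first mapped to valence-arousal quadrants through their
#' anchors.
#'
#' @param records data frame with columns `before`, `music_type`, `after`.
#' @param granularity `"emotion"` (default) or `"quadrant"`.
#' @param anchors anchor table used for the quadrant mapping.
#' @return A `"transition_table"`: a long data frame with columns `before`,
#'   `music_type`, `after`, `count`, `probability` (one row per observed
#'   cell), with granularity and per-key totals as attributes.
#' @export
transition_probabilities <- function(records, granularity = c("emotion", "quadrant"),
                                     anchors = default_emotion_anchors()) {
  granularity <- match.arg(granularity)
  need <- c("before", "music_type", "after")
  if (!is.data.frame(records) || !all(need %in% colnames(records)))
    stop_input("'records' must be a data frame with columns %s",
               paste(need, collapse = ", "))
  if (!nrow(records)) stop_input("'records' is empty")
  rec <- records[, need]
  if (granularity == "quadrant") {
    to_quad <- function(e) {
      i <- match(e, anchors$name)
      if (anyNA(i)) stop_input("emotion(s) not in anchor table: %s",
                               paste(unique(e[is.na(i)]), collapse = ", "))
      quadrant(anchors$valence[i], anchors$arousal[i])
    }
    rec$before <- to_quad(rec$before)
    rec$after <- to_quad(rec$after)
  }
  counts <- stats::aggregate(list(count = rep(1L, nrow(rec))),
                             by = rec[c("before", "music_type", "after")], FUN = sum)
  key <- interaction(counts$before, counts$music_type, drop = TRUE)
  totals <- tapply(counts$count, key, sum)
  counts$probability <- counts$count / as.numeric(totals[key])
  counts <- counts[order(counts$before, counts$music_type, counts$after), ]
  rownames(counts) <- NULL
  structure(counts, class = c("transition_table", "data.frame"),
            granularity = granularity,
            n_records = nrow(rec))
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> granularity = %s, %d records, %d nonzero cells\n",
              attr(x, "granularity"), attr(x, "n_records"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' Long-format export of a transition table
#'
#' One row per nonzero transition cell, optionally restricted to chosen
#' after-labels (the usual way to de-clutter a parallel-coordinate display).
#'
#' @param table a [transition_probabilities()] result.
#' @param after_filter optional character vector of after-labels to keep.
#' @param file optional CSV destination.
#' @return Data frame with columns `before`, `music_type`, `after`, `count`,
#'   `probability`.
#' @export
export_parallel_coordinates <- function(table, after_filter = NULL, file = NULL) {
  if (!inherits(table, "transition_table")) stop_input("'table' must be a transition_table")
  df <- as.data.frame(table)
  if (!is.null(after_filter)) {
    unknown <- setdiff(after_filter, df$after)
    if (length(unknown))
      stop_input("after_filter label(s) not present: %s", paste(unknown, collapse = ", "))
    df <- df[df$after %in% after_filter, ]
    rownames(df) <- NULL
  }
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}

#' Parallel-coordinate plot of emotion transitions
#'
#' Three axes — emotion before, music type, emotion after — with one line per
#' transition cell, line width proportional to the conditional probability.
#'
#' @param x a `"transition_table"`.
#' @param after_filter optional after-label subset.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.transition_table <- function(x, after_filter = NULL, ...) {
  df <- export_parallel_coordinates(x, after_filter)
  axes <- list(before = sort(unique(df$before)),
               music_type = sort(unique(df$music_type)),
               after = sort(unique(df$after)))
  ypos <- function(v, lev) match(v, lev) / (length(lev) + 1)
  graphics::plot(NULL, xlim = c(0.8, 3.2), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "", main = "Emotion transitions", ...)
  graphics::axis(1, 1:3, c("before", "music", "after"))
  for (i in seq_len(nrow(df))) {
    y <- c(ypos(df$before[i], axes$before), ypos(df$music_type[i], axes$music_type),
           ypos(df$after[i], axes$after))
    graphics::lines(1:3, y, lwd = 0.5 + 4 * df$probability[i],
                    col = grDevices::adjustcolor("steelblue", 0.6))
  }
  for (j in 1:3) {
    lev <- axes[[j]]
    graphics::text(rep(j, length(lev)), ypos(lev, lev), lev, cex = 0.6, pos = 4)
  }
  invisible(x)
}
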