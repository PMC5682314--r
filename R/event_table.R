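# EventTable: detected or annotated tapping intervals.
# Intervals are 0-based, half-open [start_sample, end_sample).

#' Construct an event table
#'
#' An event table lists tapping intervals — either detector output or
#' manual/ground-truth annotation — with an optional gesture label per
#' event. Intervals are 0-based half-open `[start_sample, end_sample)`,
#' sorted by start, and may not overlap within one channel scope.
#'
#' @param start_sample,end_sample Integer vectors, 0-based half-open.
#' @param label Optional labels: character or factor over
#'   [gesture_labels()], or `NA` for unlabelled events.
#' @param channel_scope `"all"` (default) or a channel index, recycled.
#' @return A `data.frame` of class `event_table`, sorted by start.
#' @export
#' @examples
#' event_table(c(100, 900), c(500, 1300), c("thumb", "index"))
event_table <- function(start_sample = integer(), end_sample = integer(),
                        label = NULL, channel_scope = "all") {
  start_sample <- as.integer(start_sample)
  end_sample <- as.integer(end_sample)
  n <- length(start_sample)
  if (length(end_sample) != n) stop_("start/end length mismatch")
  if (is.null(label)) label <- rep(NA_character_, n)
  if (any(!is.na(label) & !label %in% GESTURES))
    stop_("unknown gesture label '", label[!is.na(label) & !label %in% GESTURES][1],
          "'; valid labels are: ", paste(GESTURES, collapse = ", "))
  label <- factor(as.character(label), levels = GESTURES)
  channel_scope <- rep_len(as.character(channel_scope), n)
  if (any(start_sample < 0)) stop_("negative start_sample")
  bad <- which(start_sample >= end_sample)
  if (length(bad) > 0)
    stop_("event ", bad[1], " has start_sample >= end_sample (",
          start_sample[bad[1]], " >= ", end_sample[bad[1]], ")")
  df <- data.frame(start_sample = start_sample, end_sample = end_sample,
                   label = label, channel_scope = channel_scope,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_sample, df$end_sample), , drop = FALSE]
  rownames(df) <- NULL
  for (scope in unique(df$channel_scope)) {
    d <- df[df$channel_scope == scope, ]
    if (nrow(d) > 1 && any(d$start_sample[-1] < d$end_sample[-nrow(d)]))
      stop_("overlapping events within channel scope '", scope, "'")
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d event(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Read an event table from CSV
#'
#' Expects a header `start_sample,end_sample,label`; the label column is
#' optional and empty strings are treated as unlabelled. Inverse of
#' [write_event_table()].
#'
#' @param path File path.
#' @return An [event_table()].
#' @export
read_event_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = detect_sep(path),
                   colClasses = "character")
  need <- c("start_sample", "end_sample")
  if (!all(need %in% names(df)))
    stop_("event table must have columns start_sample,end_sample; found: ",
          paste(names(df), collapse = ", "))
  lab <- if ("label" %in% names(df)) {
    l <- df$label
    l[!nzchar(l)] <- NA_character_
    l
  } else NULL
  event_table(as.integer(df$start_sample), as.integer(df$end_sample), lab)
}

#' Write an event table to CSV
#'
#' Writes `start_sample,end_sample,label`; unlabelled events get an
#' empty label field. Exact inverse of [read_event_table()].
#'
#' @param events An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  lab <- as.character(events$label)
  lab[is.na(lab)] <- ""
  lines <- paste(events$start_sample, events$end_sample, lab, sep = ",")
  writeLines(c("start_sample,end_sample,label", lines), path)
  invisible(path)
}
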