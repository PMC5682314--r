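# Recording: a uniformly sampled multichannel MMG signal.
#
# Samples are stored time-in-rows, one column per channel. All sample
# indices in the public interface are 0-based, and intervals are
# half-open [start, end), matching the event-table convention.

#' Construct a Recording
#'
#' A `mmg_recording` holds a uniformly sampled multichannel acceleration
#' signal together with its sampling rate and the rest-period interval
#' used to calibrate detection thresholds.
#'
#' @param samples Numeric matrix, one column per channel, one row per
#'   sample. A plain vector is treated as a single channel.
#' @param sampling_rate Samples per second (Hz).
#' @param subject_id Opaque identifier string.
#' @param baseline_interval Integer pair `(start, end)`: 0-based,
#'   half-open sample interval during which the forearm is known to be
#'   at rest. Detection thresholds are calibrated on this interval.
#' @return An object of class `mmg_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2000), ncol = 2), sampling_rate = 1000,
#'                  baseline_interval = c(0, 500))
#' n_samples(rec)
recording <- function(samples, sampling_rate, subject_id = "unknown",
                      baseline_interval = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_("`samples` must be a numeric matrix (time in rows, channels in columns)")
  if (anyNA(samples)) {
    bad <- which(rowSums(is.na(samples)) > 0)[1]
    stop_("NaN/NA sample at row ", bad)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop_("`sampling_rate` must be a positive scalar")
  n <- nrow(samples)
  if (is.null(baseline_interval)) baseline_interval <- c(0L, 0L)
  b <- as.integer(baseline_interval)
  if (length(b) != 2 || b[1] < 0 || b[1] > b[2] || b[2] > n)
    stop_("`baseline_interval` must satisfy 0 <= start <= end <= n_samples")
  if (is.null(colnames(samples))) colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate),
                 subject_id = subject_id, baseline_interval = b),
            class = "mmg_recording")
}

#' @rdname recording
#' @param rec A `mmg_recording`.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' @rdname recording
#' @export
n_channels <- function(rec) ncol(rec$samples)

#' Extract one channel of a recording as a numeric vector
#'
#' @param rec A `mmg_recording`.
#' @param channel Channel index (1-based column index).
#' @return Numeric vector of samples.
#' @export
channel_signal <- function(rec, channel) {
  if (channel < 1 || channel > n_channels(rec)) stop_("channel out of range")
  rec$samples[, channel]
}

#' @export
print.mmg_recording <- function(x, ...) {
  cat(sprintf("<mmg_recording> subject '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, n_channels(x), n_samples(x), x$sampling_rate,
              n_samples(x) / x$sampling_rate))
  cat(sprintf("  baseline interval: [%d, %d)\n",
              x$baseline_interval[1], x$baseline_interval[2]))
  invisible(x)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a multichannel signal file
#'
#' Reads a delimited text file (CSV or TSV, auto-detected) with a header
#' row naming a `time_s` column followed by one column per channel
#' (`ch1`, `ch2`, ...). Time stamps must be strictly increasing with a
#' constant sampling interval; the sampling rate is inferred from it.
#'
#' @param path File path.
#' @param subject_id Identifier stored on the recording.
#' @param baseline_interval Optional rest interval, 0-based half-open
#'   sample indices.
#' @return A [recording()].
#' @export
read_recording <- function(path, subject_id = "unknown", baseline_interval = NULL) {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop_("signal file must have a 'time_s' column; found: ",
          paste(names(df), collapse = ", "))
  ch_cols <- setdiff(names(df), "time_s")
  if (length(ch_cols) < 1) stop_("signal file has no channel columns")
  t <- df$time_s
  if (anyNA(t)) stop_("missing time stamp at row ", which(is.na(t))[1])
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1]
    stop_("non-monotone or duplicated time stamp at row ", bad + 1L)
  }
  dt0 <- median(dt)
  irregular <- which(abs(dt - dt0) > 1e-6 * dt0)
  if (length(irregular) > 0)
    stop_("non-uniform sampling interval at row ", irregular[1] + 1L,
          " (expected ", format(dt0), ", got ", format(dt[irregular[1]]), ")")
  m <- as.matrix(df[ch_cols])
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop_("NaN/missing sample at row ", bad)
  }
  recording(m, sampling_rate = 1 / dt0, subject_id = subject_id,
            baseline_interval = baseline_interval %||% c(0L, 0L))
}

#' Write a recording to a delimited signal file
#'
#' Writes `time_s,ch1,ch2,...` CSV at full double precision, so that
#' `read_recording(write_recording(rec, path))` reproduces the samples
#' exactly.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- n_samples(rec)
  t <- (seq_len(n) - 1) / rec$sampling_rate
  cols <- c(list(sprintf("%.17g", t)),
            lapply(seq_len(n_channels(rec)),
                   function(j) sprintf("%.17g", rec$samples[, j])))
  header <- paste(c("time_s", colnames(rec$samples)), collapse = ",")
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, lines), path)
  invisible(path)
}
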