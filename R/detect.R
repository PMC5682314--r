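# Tapping-event detection (TED).
#
# Two detectors: a sliding RMS envelope thresholded at alpha_r times its
# rest-period mean, and a difference-template convolution (DTF) whose
# rectified response is thresholded at alpha_d times its rest-period
# mean. Both calibrate the threshold on a known rest interval of the
# recording.

#' Detector specification
#'
#' @param algorithm `"rms"` (sliding root-mean-square envelope) or
#'   `"dtf"` (difference-template convolution).
#' @param window RMS window length `W` in samples (default 400, i.e.
#'   400 ms at 1 kHz). Ignored by the DTF detector.
#' @param alpha Threshold scaling factor. Defaults to 2.15 for `"rms"`
#'   and 2 for `"dtf"`.
#' @param rectify DTF only: threshold the absolute response (default
#'   `TRUE`). The raw template response is zero-mean at rest, which makes
#'   a mean-based threshold degenerate; rectification restores a
#'   meaningful rest-level calibration.
#' @param min_event_duration Minimum event length in samples; shorter
#'   above-threshold runs are discarded (default 100).
#' @param merge_gap Above-threshold runs separated by fewer than this
#'   many samples are merged before the duration check. Defaults to 200
#'   for `"rms"` and 50 for `"dtf"`: the DTF merge gap only needs to
#'   bridge the rectified carrier's zero-crossing dips (at most half a
#'   carrier period, 50 ms at 10 Hz); a longer gap would glue isolated
#'   rest-noise blips onto event boundaries.
#' @param channel_combination `"or"` (default: a sample is active if any
#'   channel is active), `"and"`, or a channel index to use one channel.
#' @param smooth DTF only: length (samples) of the centred moving
#'   average applied to the rectified template response before
#'   thresholding (default 200, well below the shortest tap burst so
#'   bursts are not washed out; 0 disables it). The rectified response
#'   of rest noise is a half-normal series whose sample-wise exceedance
#'   of twice its own mean is scale-free (about 11% for Gaussian noise),
#'   so the literal sample-wise comparison cannot separate rest from
#'   taps at any SNR; averaging concentrates the rest response around
#'   its mean — the very quantity the threshold is calibrated on, which
#'   the moving average leaves unchanged — while burst responses stay
#'   far above it.
#' @param recenter RMS only: if `TRUE`, compensate the forward-looking
#'   window's lead by shifting each event's start forward by `window`
#'   samples (the envelope at `t` summarises `[t, t+W)`, so the first
#'   above-threshold window starts up to `W` samples before the
#'   activity). Default `FALSE`: boundaries are reported in raw
#'   window-start coordinates.
#' @return A list of class `detector_spec`.
#' @export
detector_spec <- function(algorithm = c("rms", "dtf"), window = 400L,
                          alpha = NULL, rectify = TRUE,
                          min_event_duration = 100L, merge_gap = NULL,
                          channel_combination = "or", smooth = 200L,
                          recenter = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(alpha)) alpha <- if (algorithm == "rms") 2.15 else 2
  if (is.null(merge_gap)) merge_gap <- if (algorithm == "rms") 200L else 50L
  if (alpha <= 0) stop_("`alpha` must be positive")
  window <- as.integer(window)
  if (window < 1) stop_("`window` must be >= 1")
  if (min_event_duration < 1) stop_("`min_event_duration` must be >= 1")
  structure(list(algorithm = algorithm, window = window, alpha = alpha,
                 rectify = isTRUE(rectify),
                 min_event_duration = as.integer(min_event_duration),
                 merge_gap = as.integer(merge_gap),
                 channel_combination = channel_combination,
                 smooth = as.integer(smooth),
                 recenter = isTRUE(recenter)),
            class = "detector_spec")
}

# Centred moving average with partial windows at the edges.
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding RMS envelope
#'
#' `g[t] = sqrt(mean(x[t .. t+W-1]^2))` for `t = 0 .. n-W-1` (0-based,
#' forward-looking window of `W` samples). The output has `length(x) - W`
#' values.
#'
#' @param x Numeric signal vector.
#' @param window Window length `W` in samples.
#' @return Nonnegative numeric vector of length `length(x) - window`.
#' @export
#' @examples
#' rms_envelope(rep(3, 100), 10)  # all values exactly 3
rms_envelope <- function(x, window) {
  n <- length(x)
  W <- as.integer(window)
  if (W >= n) stop_("window (", W, ") must be smaller than the signal length (", n, ")")
  cs <- c(0, cumsum(x^2))
  out <- sqrt(pmax((cs[(W + 1):(n)] - cs[1:(n - W)]) / W, 0))
  out
}

#' Rest-calibrated detection threshold
#'
#' `TH = alpha * mean(g[baseline])`: the mean of the envelope (or
#' rectified template response) over the known rest interval, scaled by
#' `alpha` (2.15 for the RMS detector, 2 for the DTF detector).
#'
#' @param g Envelope or response series.
#' @param baseline Integer pair `(start, end)`: 0-based half-open index
#'   interval into `g` covering the rest period.
#' @param alpha Threshold scaling factor.
#' @return Scalar threshold. A zero threshold (all-zero rest response)
#'   triggers a warning: every nonzero sample would then be active.
#' @export
detection_threshold <- function(g, baseline, alpha) {
  s <- as.integer(baseline[1]); e <- as.integer(baseline[2])
  if (e <= s) stop_("empty baseline interval")
  if (s < 0 || e > length(g))
    stop_("baseline interval [", s, ", ", e, ") outside envelope range [0, ",
          length(g), ")")
  th <- alpha * mean(g[(s + 1):e])
  if (th == 0) warning("degenerate threshold: rest-interval response is identically zero")
  th
}

#' @rdname detection_threshold
#' @export
rms_threshold <- detection_threshold

#' @rdname detection_threshold
#' @export
dtf_threshold <- detection_threshold

#' The difference template
#'
#' The fixed 17-tap template `D = [-1 x8, 0, +1 x8]` convolved with the
#' signal to emphasise onset/offset transitions.
#'
#' @return Numeric vector of length 17.
#' @export
dtf_template <- function() c(rep(-1, 8), 0, rep(1, 8))

#' Difference-template response
#'
#' Linear convolution of the signal with [dtf_template()], aligned
#' 'same'-length with the template's central zero element, so the
#' response at `t` contrasts the 8 samples before `t` against the 8
#' samples after it. With `rectify = TRUE` (default) the absolute value
#' is returned.
#'
#' @param x Numeric signal vector (length >= 17).
#' @param rectify Return `|g|` instead of the signed response.
#' @return Numeric vector the same length as `x`.
#' @export
dtf_response <- function(x, rectify = TRUE) {
  D <- dtf_template()
  n <- length(x)
  if (n < length(D)) stop_("signal shorter than the 17-tap template")
  # full linear convolution, then the 'same' slice centred on D's zero
  full <- stats::convolve(x, rev(D), type = "open")
  g <- full[(1 + 8):(n + 8)]
  if (rectify) abs(g) else g
}

#' Threshold an activity series and segment it into events
#'
#' `Z[t] = 1` iff `g[t] > TH`. Events are the maximal runs of `Z = 1`,
#' after merging runs separated by gaps shorter than `merge_gap` and
#' then discarding runs shorter than `min_event_duration`. Event
#' boundaries are half-open: start is the first above-threshold sample,
#' end the first below-threshold sample after the run.
#'
#' @param g Envelope or response series.
#' @param threshold Scalar threshold `TH`.
#' @param spec A [detector_spec()] supplying `merge_gap` and
#'   `min_event_duration`.
#' @return A list of class `detection_result`: `activation` (logical),
#'   `envelope`, `threshold`, and `events` (an [event_table()]).
#' @export
binarize_and_segment <- function(g, threshold, spec = detector_spec()) {
  if (!is.finite(threshold)) stop_("threshold must be finite")
  z <- g > threshold
  ev <- activation_to_events(z, spec$merge_gap, spec$min_event_duration)
  structure(list(activation = z, envelope = g, threshold = threshold,
                 events = ev),
            class = "detection_result")
}

# maximal TRUE runs of z -> event_table, with gap merging then
# minimum-duration filtering (in that order)
activation_to_events <- function(z, merge_gap, min_event_duration) {
  r <- rle(as.logical(z))
  ends <- cumsum(r$lengths)            # 1-based inclusive run ends
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0) return(event_table())
  s <- starts[on] - 1L                 # 0-based half-open
  e <- ends[on]
  if (length(s) > 1 && merge_gap > 0) {
    keep_s <- s[1]; out_s <- integer(); out_e <- integer(); cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] - cur_e < merge_gap) {
        cur_e <- e[i]
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- s[i]; cur_e <- e[i]
      }
    }
    out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
    s <- out_s; e <- out_e
  }
  keep <- (e - s) >= min_event_duration
  event_table(s[keep], e[keep])
}

#' Detect tapping events in a recording
#'
#' Runs the configured detector on every channel of a (typically
#' band-pass filtered) recording, calibrates one threshold per channel
#' on the recording's `baseline_interval`, combines the per-channel
#' activation series (`"or"`/`"and"`/single channel), and segments the
#' combined activation into events.
#'
#' @param rec A [recording()] with a nonempty `baseline_interval`.
#' @param spec A [detector_spec()].
#' @return A `detection_result` whose `envelope` and `threshold` hold
#'   per-channel values (matrix columns / vector entries).
#' @export
detect_events <- function(rec, spec = detector_spec()) {
  C <- n_channels(rec)
  b <- rec$baseline_interval
  if (b[2] <= b[1]) stop_("recording has no baseline (rest) interval")
  env <- vector("list", C); th <- numeric(C)
  for (j in seq_len(C)) {
    x <- channel_signal(rec, j)
    if (spec$algorithm == "rms") {
      g <- rms_envelope(x, spec$window)
      look_ahead <- spec$window
    } else {
      g <- dtf_response(x, rectify = spec$rectify)
      if (spec$smooth > 1) g <- moving_average(g, spec$smooth)
      look_ahead <- (length(dtf_template()) - 1L) %/% 2L + spec$smooth %/% 2L
    }
    # only envelope values whose windows lie wholly inside the rest
    # period are "during rest"; windows reaching past its end would leak
    # the first tap into the threshold calibration
    bl <- c(b[1], min(b[2] - look_ahead, length(g)))
    if (bl[2] <= bl[1]) bl <- c(b[1], min(b[2], length(g)))
    th[j] <- detection_threshold(g, bl, spec$alpha)
    env[[j]] <- g
  }
  len <- min(lengths(env))
  zmat <- vapply(seq_len(C), function(j) env[[j]][seq_len(len)] > th[j],
                 logical(len))
  comb <- spec$channel_combination
  z <- if (identical(comb, "or")) rowSums(zmat) > 0
       else if (identical(comb, "and")) rowSums(zmat) == ncol(zmat)
       else zmat[, as.integer(comb)]
  ev <- activation_to_events(z, spec$merge_gap, spec$min_event_duration)
  if (spec$algorithm == "rms" && spec$recenter && nrow(ev) > 0) {
    # window-start run [t0, t1) means windows [t0, t0+W) .. [t1-1, t1-1+W)
    # saw activity; the activity interval itself is ~[t0+W, t1) at high
    # SNR (guarded so the interval stays nonempty)
    s <- pmin(ev$start_sample + spec$window, ev$end_sample - 1L)
    ev <- event_table(s, ev$end_sample, ev$label)
  }
  structure(list(activation = z,
                 envelope = do.call(cbind, lapply(env, function(g) g[seq_len(len)])),
                 threshold = th, events = ev, spec = spec),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d event(s), threshold(s): %s\n",
              nrow(x$events), paste(signif(x$threshold, 4), collapse = ", ")))
  invisible(x)
}

#' Extract fixed-length segments around events
#'
#' Each segment is `segment_length` samples per channel, centred on the
#' event's midpoint (half-open window). Portions falling outside the
#' recording are zero-padded; events longer than `segment_length` are
#' truncated symmetrically.
#'
#' @param rec A [recording()].
#' @param events An [event_table()].
#' @param segment_length Samples per segment (`LN`); must be a positive
#'   multiple of 32.
#' @return A list of segments; each has `samples` (matrix
#'   `segment_length` x channels), `start`/`end` (the covered 0-based
#'   window, possibly out of recording range where zero-padded), and
#'   `label`.
#' @export
extract_segments <- function(rec, events, segment_length = 1024L) {
  LN <- as.integer(segment_length)
  if (LN <= 0 || LN %% 32 != 0) stop_("`segment_length` must be a positive multiple of 32")
  n <- n_samples(rec)
  lapply(seq_len(nrow(events)), function(i) {
    s <- events$start_sample[i]; e <- events$end_sample[i]
    if (e <= 0 || s >= n) stop_("event ", i, " lies entirely outside the recording")
    mid <- (s + e) %/% 2L
    w0 <- mid - LN %/% 2L
    w1 <- w0 + LN
    seg <- matrix(0, nrow = LN, ncol = n_channels(rec),
                  dimnames = list(NULL, colnames(rec$samples)))
    src0 <- max(w0, 0L); src1 <- min(w1, n)
    if (src1 > src0)
      seg[(src0 - w0 + 1):(src1 - w0), ] <- rec$samples[(src0 + 1):src1, , drop = FALSE]
    list(samples = seg, start = w0, end = w1, label = events$label[i])
  })
}
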