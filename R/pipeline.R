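# End-to-end pipeline orchestration: signal file -> band-pass ->
# event annotation (automatic or manual) -> segments -> wavelet-packet
# SVD features -> per-fold ranking/selection -> cross-validated
# classification -> evaluation report.

#' Run the full recognition pipeline
#'
#' In manual mode (`events_path` given) segmentation uses the supplied
#' labelled event table and the detection stage is bypassed; no FDER is
#' reported. In automatic mode events are detected from the filtered
#' signal; when `truth_path` is given, detection is scored against it
#' (FDER) and detected events inherit the label of their matched truth
#' event (unmatched detections are excluded from classification).
#'
#' @param config A [pipeline_config()].
#' @param signal_path Signal CSV/TSV (see [read_recording()]).
#' @param events_path Optional labelled event table (manual mode).
#' @param truth_path Optional ground-truth event table for automatic
#'   mode.
#' @param baseline_interval 0-based half-open rest interval in samples,
#'   required in automatic mode.
#' @return An `evaluation_report` (see [cross_validate()]) augmented
#'   with `mode`, `n_events`, `events`, `fder` (automatic mode with
#'   truth only) and the resolved `config`.
#' @export
run_pipeline <- function(config, signal_path, events_path = NULL,
                         truth_path = NULL, baseline_interval = NULL) {
  rec <- read_recording(signal_path, baseline_interval = baseline_interval)
  fspec <- filter_spec(order = config$filter$order, low = config$filter$low,
                       high = config$filter$high,
                       zero_phase = config$filter$zero_phase)
  filt <- bandpass_filter(rec, fspec)
  fder <- NULL
  if (!is.null(events_path)) {
    mode <- "manual"
    events <- read_event_table(events_path)
  } else {
    mode <- "auto"
    d <- config$detector
    dspec <- detector_spec(algorithm = d$algorithm, window = d$window,
                           alpha = d$alpha, rectify = d$rectify,
                           min_event_duration = d$min_event_duration,
                           merge_gap = d$merge_gap, smooth = d$smooth,
                           channel_combination = d$channel_combination)
    det <- detect_events(filt, dspec)
    events <- det$events
    if (!is.null(truth_path)) {
      truth <- read_event_table(truth_path)
      fder <- compute_fder(events, truth, tol = d$match_tol)
      lab <- rep(NA_character_, nrow(events))
      lab[fder$matches$detected] <- as.character(truth$label[fder$matches$truth])
      events <- event_table(events$start_sample, events$end_sample, lab)
    }
  }
  labelled <- events[!is.na(events$label), , drop = FALSE]
  class(labelled) <- class(events)
  if (length(unique(labelled$label[!is.na(labelled$label)])) < 2)
    stop_("fewer than 2 gesture classes present after segmentation; ",
          "classification is undefined")
  segments <- extract_segments(filt, labelled, config$segment_length)
  feats <- featurize_segments(segments, wavelet = config$wavelet,
                              level = config$level)
  report <- cross_validate(feats$features, feats$labels,
                           spec = do.call(classifier_spec, config$classifier),
                           folds = config$folds, seed = config$seed,
                           k_per_channel = config$k_per_channel,
                           channel_map = feats$channel_map,
                           ranking_convention = config$ranking_convention)
  report$mode <- mode
  report$n_events <- nrow(events)
  report$events <- as.data.frame(events)
  if (!is.null(fder)) report$fder <- fder$fder
  if (!is.null(fder)) report$fder_counts <- fder[c("n_fp", "n_fn", "n_all")]
  report$config <- unclass(config)
  report
}

#' Serialise an evaluation report to JSON
#'
#' Deterministic serialisation (fixed 15 significant digits, stable
#' field order): identical reports produce byte-identical files.
#'
#' @param report An `evaluation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  r$confusion <- as.data.frame.matrix(r$confusion)
  if (!is.null(r$events)) r$events$label <- as.character(r$events$label)
  json <- jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(15),
                           pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}
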