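# Pipeline configuration: one object aggregating every stage's
# parameters, serialisable to YAML so that each report can embed the
# exact configuration that produced it.

CONFIG_SCHEMA_VERSION <- 1L

#' Construct a pipeline configuration
#'
#' Aggregates all tunable parameters of the recognition pipeline. The
#' defaults are the operating point of the method: 0.1–50 Hz 4th-order
#' Butterworth band-pass, 400 ms RMS detection window with threshold
#' scale 2.15 (or difference-template detection with scale 2), 1024-sample
#' segments, level-5 db4 wavelet-packet decomposition, 4 features per
#' channel after F-value ranking, and 5-fold stratified cross-validation.
#'
#' @param filter List: `order` (total poles, default 4), `low`, `high`
#'   cutoffs in Hz, `zero_phase` (default `TRUE`).
#' @param detector List: see [detector_spec()] for fields and defaults.
#' @param segment_length Samples per extracted segment (`LN`); must be a
#'   positive multiple of `2^level`.
#' @param wavelet Orthogonal wavelet family name (see [wavelet_filters()]).
#' @param level Wavelet-packet decomposition depth (default 5, giving
#'   32 leaves).
#' @param k_per_channel Number of top-ranked features kept per channel.
#' @param ranking_convention `"fisher"` (between/within, default) or
#'   `"as_printed"` (within/between).
#' @param classifier List: `kind` one of `"nbc"`, `"knn"`, `"svm"` plus
#'   the fields of [classifier_spec()].
#' @param folds Stratified cross-validation fold count.
#' @param seed Integer random seed governing all pipeline randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = list(), detector = list(),
                            segment_length = 1024L, wavelet = "db4",
                            level = 5L, k_per_channel = 4L,
                            ranking_convention = c("fisher", "as_printed"),
                            classifier = list(), folds = 5L, seed = 1L) {
  ranking_convention <- match.arg(ranking_convention)
  filter <- utils::modifyList(
    list(order = 4L, low = 0.1, high = 50, zero_phase = TRUE), filter)
  detector <- utils::modifyList(
    list(algorithm = "rms", window = 400L, rectify = TRUE,
         min_event_duration = 100L, channel_combination = "or",
         match_tol = 400L), detector)
  # resolve algorithm-dependent defaults eagerly so the config
  # serialises without holes
  if (is.null(detector$alpha))
    detector$alpha <- if (detector$algorithm == "rms") 2.15 else 2
  if (is.null(detector$merge_gap))
    detector$merge_gap <- if (detector$algorithm == "rms") 200L else 50L
  if (is.null(detector$smooth))
    detector$smooth <- if (detector$algorithm == "rms") 0L else 200L
  classifier <- utils::modifyList(
    list(kind = "nbc", knn_k = 5L, cost = 1, gamma = 1, coef0 = 0,
         degree = 3L), classifier)
  if (is.null(classifier$standardize))
    classifier$standardize <- classifier$kind %in% c("knn", "svm")
  level <- as.integer(level)
  segment_length <- as.integer(segment_length)
  if (level < 1) stop_("`level` must be >= 1")
  if (segment_length <= 0 || segment_length %% (2^level) != 0)
    stop_("`segment_length` must be a positive multiple of 2^level = ", 2^level)
  n_leaves <- 2^level
  if (k_per_channel < 1 || k_per_channel > n_leaves)
    stop_("`k_per_channel` must be in 1..", n_leaves)
  cfg <- list(schema_version = CONFIG_SCHEMA_VERSION, filter = filter,
              detector = detector, segment_length = segment_length,
              wavelet = wavelet, level = level,
              k_per_channel = as.integer(k_per_channel),
              ranking_convention = ranking_convention,
              classifier = classifier, folds = as.integer(folds),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> schema", x$schema_version, "\n")
  cat(sprintf("  filter: order-%d Butterworth band-pass %g-%g Hz (%s)\n",
              x$filter$order, x$filter$low, x$filter$high,
              if (isTRUE(x$filter$zero_phase)) "zero-phase" else "causal"))
  cat(sprintf("  detector: %s, window %d, alpha %s\n", x$detector$algorithm,
              x$detector$window, format(x$detector$alpha %||% "default")))
  cat(sprintf("  features: LN=%d, %s level %d, k=%d/channel (%s ranking)\n",
              x$segment_length, x$wavelet, x$level, x$k_per_channel,
              x$ranking_convention))
  cat(sprintf("  classifier: %s, %d-fold CV, seed %d\n",
              x$classifier$kind, x$folds, x$seed))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML schema is versioned; files with a different
#' `schema_version` are rejected.
#'
#' @param path File path.
#' @return `read_config()` returns a [pipeline_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != CONFIG_SCHEMA_VERSION)
    stop_("unsupported config schema_version: ",
          y$schema_version %||% "<missing>", " (expected ",
          CONFIG_SCHEMA_VERSION, ")")
  y$schema_version <- NULL
  do.call(pipeline_config, y)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
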