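# Feature compression and ranking.
#
# Each segment/channel is summarised by the singular values of its
# wavelet-packet feature matrix (a fixed-length, shift- and
# rotation-insensitive energy profile), then features are ordered by a
# within/between-class distance ratio computed per feature.

#' Singular-value compression of a feature matrix
#'
#' Returns the singular values of the wavelet-packet feature matrix in
#' descending order — the compressed per-channel feature vector (32
#' values for a level-5 decomposition).
#'
#' @param X Numeric matrix with at least as many rows as columns.
#' @return Nonnegative numeric vector, descending, of length `ncol(X)`.
#' @export
svd_compress <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop_("`X` must be a numeric matrix")
  if (anyNA(X)) stop_("`X` contains NaN/NA values")
  if (nrow(X) < ncol(X))
    stop_("feature matrix needs nrow >= ncol (", nrow(X), " < ", ncol(X), ")")
  svd(X, nu = 0, nv = 0)$d
}

#' Compute singular-value features for extracted segments
#'
#' For every segment and channel: wavelet-packet decomposition to
#' `level`, leaf stacking into the feature matrix, and singular-value
#' compression. Per-channel feature vectors are concatenated in channel
#' order (channel 1's 32 values, then channel 2's, ...).
#'
#' @param segments List of segments from [extract_segments()].
#' @param wavelet,level Passed to [wpt_decompose()].
#' @return List with `features` (matrix, one row per segment),
#'   `channel_map` (integer vector assigning each column to a channel)
#'   and `labels` (factor, `NA` where the segment was unlabelled).
#' @export
featurize_segments <- function(segments, wavelet = "db4", level = 5L) {
  if (length(segments) == 0) stop_("no segments to featurise")
  n_leaves <- 2^level
  C <- ncol(segments[[1]]$samples)
  rows <- lapply(segments, function(seg) {
    unlist(lapply(seq_len(C), function(j) {
      X <- build_feature_matrix(wpt_decompose(seg$samples[, j], level, wavelet))
      svd_compress(X)
    }))
  })
  features <- do.call(rbind, rows)
  colnames(features) <- paste0("ch", rep(seq_len(C), each = n_leaves),
                               "_sv", rep(seq_len(n_leaves), C))
  labels <- factor(vapply(segments, function(s) as.character(s$label),
                          character(1)), levels = GESTURES)
  list(features = features,
       channel_map = rep(seq_len(C), each = n_leaves),
       labels = labels)
}

# Mean absolute difference over ordered pairs m != n, with the
# 1/(N(N-1)) normalisation.
mean_abs_pair_dist <- function(v) {
  N <- length(v)
  sum(abs(outer(v, v, "-"))) / (N * (N - 1))
}

#' Rank features by within/between-class distance ratio
#'
#' For each feature `i`: the within-class spread `d_ai` is the mean over
#' classes of the mean absolute pairwise sample difference inside the
#' class; the between-class spread `d'_ai` is the mean absolute pairwise
#' difference of the class means. Features are scored by the ratio
#' `F = d'_ai / d_ai` (convention `"fisher"`; large F = well separated,
#' the default) or by the reciprocal `F = d_ai / d'_ai` (convention
#' `"as_printed"`), and ranked by F in descending order, ties broken by
#' lower feature index.
#'
#' Degenerate ratios: `0/0` scores 0; a zero denominator with a nonzero
#' numerator scores a large finite cap (`1e12`, with a warning) so the
#' ordering stays total.
#'
#' @param features Numeric matrix, one sample per row.
#' @param labels Factor/character class labels, one per row; every class
#'   must have at least 2 samples.
#' @param convention `"fisher"` or `"as_printed"`.
#' @return A `data.frame` of class `feature_ranking`, ordered by rank,
#'   with columns `feature`, `d_within`, `d_between`, `f_value`, `rank`.
#' @export
f_value_ranking <- function(features, labels,
                            convention = c("fisher", "as_printed")) {
  convention <- match.arg(convention)
  labels <- as_class_factor(labels)
  if (nlevels(labels) < 2) stop_("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2))
    stop_("class '", names(counts)[counts < 2][1],
          "' has fewer than 2 samples; within-class distance undefined")
  M <- nlevels(labels)
  nf <- ncol(features)
  d_within <- numeric(nf); d_between <- numeric(nf)
  for (i in seq_len(nf)) {
    v <- features[, i]
    dij <- vapply(levels(labels), function(cl) mean_abs_pair_dist(v[labels == cl]),
                  numeric(1))
    d_within[i] <- mean(dij)
    class_means <- vapply(levels(labels), function(cl) mean(v[labels == cl]),
                          numeric(1))
    d_between[i] <- mean_abs_pair_dist(class_means)
  }
  num <- if (convention == "fisher") d_between else d_within
  den <- if (convention == "fisher") d_within else d_between
  f <- numeric(nf)
  zero_den <- den == 0
  f[!zero_den] <- num[!zero_den] / den[!zero_den]
  f[zero_den & num == 0] <- 0
  capped <- zero_den & num > 0
  if (any(capped)) {
    f[capped] <- 1e12
    warning(sum(capped), " feature(s) with zero ",
            if (convention == "fisher") "within" else "between",
            "-class distance but nonzero separation; F capped at 1e12")
  }
  ord <- order(-f, seq_len(nf))
  out <- data.frame(feature = ord, d_within = d_within[ord],
                    d_between = d_between[ord], f_value = f[ord],
                    rank = seq_len(nf))
  attr(out, "convention") <- convention
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Select the top-k features per channel
#'
#' Given one [f_value_ranking()] per channel, keeps each channel's `k`
#' best features. The reduced vector is channel 1's `k` features
#' followed by channel 2's, etc.
#'
#' @param rankings List of `feature_ranking` objects, one per channel,
#'   each ranking that channel's own feature block.
#' @param k Features to keep per channel (1 to the per-channel feature
#'   count).
#' @param channel_map Integer vector assigning the columns of the full
#'   feature matrix to channels (as returned by [featurize_segments()]).
#' @return Integer vector of selected global column indices, channel 1
#'   block first.
#' @export
select_features <- function(rankings, k, channel_map) {
  per_channel <- split(seq_along(channel_map), channel_map)
  if (length(rankings) != length(per_channel))
    stop_("need one ranking per channel")
  nf <- length(per_channel[[1]])
  if (k < 1 || k > nf) stop_("`k` must be in 1..", nf)
  unlist(lapply(seq_along(rankings), function(j) {
    local_idx <- rankings[[j]]$feature[seq_len(k)]
    per_channel[[j]][local_idx]
  }))
}
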