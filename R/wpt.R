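# Wavelet-packet transform (WPT).
#
# Full binary analysis tree: every node is split by the orthonormal
# analysis pair (h = scaling, g = wavelet) with periodic boundary
# handling and dyadic downsampling. At level 5 a segment of LN samples
# yields 2^5 = 32 leaves of LN/32 coefficients each, kept in natural
# (Paley) tree order. With an orthonormal family and periodic extension
# the transform is exactly orthogonal: leaf energies sum to the segment
# energy and the inverse transform is the adjoint.

# Orthonormal scaling filters. db4's coefficients are the standard
# published values; db1/db2 are closed forms.
DB_FILTERS <- list(
  db1 = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.230377813308855230, 0.714846570552541500,
          0.630880767929590400, -0.027983769416983850,
          -0.187034811718881140, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

#' Analysis filters of an orthogonal wavelet family
#'
#' Returns the scaling (low-pass) filter `h` and the quadrature-mirror
#' wavelet filter `g[k] = (-1)^k h[L-1-k]` of a supported orthonormal
#' Daubechies family.
#'
#' @param wavelet Family name: one of `"haar"`/`"db1"`, `"db2"`, `"db4"`.
#' @return List with numeric vectors `h` and `g`.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  name <- if (identical(wavelet, "haar")) "db1" else wavelet
  h <- DB_FILTERS[[name]]
  if (is.null(h))
    stop_("unknown wavelet '", wavelet, "'; supported families: ",
          paste(c("haar", names(DB_FILTERS)), collapse = ", "))
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * h[L:1]
  list(h = h, g = g)
}

# One periodized analysis step: out[k] = sum_m f[m] x[(2k + m) mod n],
# k = 0..n/2-1 (0-based). Vectorised over k.
wpt_step <- function(x, f) {
  n <- length(x)
  k2 <- seq.int(0L, n - 2L, by = 2L)
  out <- numeric(n / 2)
  for (m in seq_along(f)) out <- out + f[m] * x[((k2 + m - 1L) %% n) + 1L]
  out
}

# Adjoint (synthesis) of one step.
wpt_unstep <- function(a, d, h, g) {
  n <- 2L * length(a)
  x <- numeric(n)
  k2 <- seq.int(0L, n - 2L, by = 2L)
  for (m in seq_along(h)) {
    idx <- ((k2 + m - 1L) %% n) + 1L
    contrib <- h[m] * a + g[m] * d
    # idx values are unique within one m (stride-2 shifts), so plain
    # indexed addition is safe
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Wavelet-packet decomposition of a segment
#'
#' Decomposes a segment down a full binary tree of depth `level`,
#' returning the `2^level` leaf coefficient vectors in natural (Paley)
#' order: the two children of node `p` are the scaling-filtered
#' (`2p - 1`) and wavelet-filtered (`2p`) halves, left to right.
#'
#' @param x Numeric segment whose length is a multiple of `2^level`.
#' @param level Decomposition depth (default 5).
#' @param wavelet Family name accepted by [wavelet_filters()].
#' @return List of `2^level` numeric vectors, each of length
#'   `length(x) / 2^level`.
#' @export
#' @examples
#' leaves <- wpt_decompose(rnorm(1024), level = 5)
#' length(leaves)           # 32
#' lengths(leaves)[1]       # 32
wpt_decompose <- function(x, level = 5L, wavelet = "db4") {
  fl <- wavelet_filters(wavelet)
  level <- as.integer(level)
  if (length(x) %% 2^level != 0)
    stop_("segment length ", length(x), " is not a multiple of 2^level = ", 2^level)
  nodes <- list(x)
  for (j in seq_len(level)) {
    nodes <- unlist(lapply(nodes, function(nd)
      list(wpt_step(nd, fl$h), wpt_step(nd, fl$g))), recursive = FALSE)
  }
  nodes
}

#' Inverse wavelet-packet transform
#'
#' Reconstructs a segment from its leaf coefficients (the adjoint of
#' [wpt_decompose()]; exact for the orthonormal families).
#'
#' @param leaves List of `2^level` equal-length leaf vectors in natural
#'   order.
#' @param wavelet Family name used for the decomposition.
#' @return Numeric vector of length `length(leaves[[1]]) * 2^level`.
#' @export
wpt_reconstruct <- function(leaves, wavelet = "db4") {
  fl <- wavelet_filters(wavelet)
  nodes <- leaves
  while (length(nodes) > 1) {
    nodes <- lapply(seq_len(length(nodes) / 2), function(p)
      wpt_unstep(nodes[[2 * p - 1]], nodes[[2 * p]], fl$h, fl$g))
  }
  nodes[[1]]
}

#' Stack wavelet-packet leaves into the feature matrix
#'
#' Column `p` of the feature matrix holds leaf `p`, giving a
#' `(LN / 2^level) x 2^level` matrix (with the default LN = 1024 and
#' level 5: 32 x 32).
#'
#' @param leaves List of equal-length leaf vectors from
#'   [wpt_decompose()].
#' @return Numeric matrix, one leaf per column.
#' @export
build_feature_matrix <- function(leaves) {
  len <- lengths(leaves)
  if (length(unique(len)) != 1) stop_("ragged leaves: lengths ",
                                      paste(unique(len), collapse = ", "))
  do.call(cbind, leaves)
}
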