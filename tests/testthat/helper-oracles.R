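# Independent brute-force oracles used across the suite. These
# deliberately re-derive every quantity from its definition with plain
# loops, sharing no code path with the package implementation.

# sliding RMS by direct summation
naive_rms <- function(x, W) {
  n <- length(x)
  vapply(seq_len(n - W), function(t) sqrt(sum(x[t:(t + W - 1)]^2) / W),
         numeric(1))
}

# template response by direct convolution sum, aligned on the template's
# zero (9th) element: g[t] = sum_k D[k] * x[t + 9 - k]
naive_dtf <- function(x, D = c(rep(-1, 8), 0, rep(1, 8))) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    acc <- 0
    for (k in seq_along(D)) {
      i <- t + 9L - k
      if (i >= 1 && i <= n) acc <- acc + D[k] * x[i]
    }
    acc
  }, numeric(1))
}

# one periodized analysis step evaluated sample by sample
naive_wpt_step <- function(x, f) {
  n <- length(x)
  out <- numeric(n / 2)
  for (k in 0:(n / 2 - 1)) {
    acc <- 0
    for (m in seq_along(f)) acc <- acc + f[m] * x[((2 * k + m - 1) %% n) + 1]
    out[k + 1] <- acc
  }
  out
}

# full filter-bank cascade: recursive splitting in natural order
naive_wpt_cascade <- function(x, level, h, g) {
  if (level == 0) return(list(x))
  c(naive_wpt_cascade(naive_wpt_step(x, h), level - 1, h, g),
    naive_wpt_cascade(naive_wpt_step(x, g), level - 1, h, g))
}

# Eqs for the distance-ratio ranking, nested loops over samples
naive_f_values <- function(features, labels, convention = "fisher") {
  labels <- factor(labels)
  cls <- levels(labels)
  M <- length(cls)
  nf <- ncol(features)
  out <- data.frame(feature = seq_len(nf), d_within = NA_real_,
                    d_between = NA_real_, f = NA_real_)
  for (i in seq_len(nf)) {
    dij <- numeric(M)
    means <- numeric(M)
    for (j in seq_len(M)) {
      p <- features[labels == cls[j], i]
      N <- length(p)
      acc <- 0
      for (m in seq_len(N)) for (n in seq_len(N))
        if (m != n) acc <- acc + abs(p[m] - p[n])
      dij[j] <- acc / (N * (N - 1))
      means[j] <- sum(p) / N
    }
    d_ai <- mean(dij)
    acc <- 0
    for (m in seq_len(M)) for (n in seq_len(M))
      if (m != n) acc <- acc + abs(means[m] - means[n])
    d_pai <- acc / (M * (M - 1))
    f <- if (convention == "fisher") {
      if (d_ai == 0 && d_pai == 0) 0
      else if (d_ai == 0) 1e12
      else d_pai / d_ai
    } else {
      if (d_pai == 0 && d_ai == 0) 0
      else if (d_pai == 0) 1e12
      else d_ai / d_pai
    }
    out$d_within[i] <- d_ai; out$d_between[i] <- d_pai; out$f[i] <- f
  }
  out
}

# exhaustive optimal one-to-one event matching (maximise matched pairs)
# for small tables; returns the maximum number of matchable pairs
optimal_match_count <- function(mid_d, mid_t, tol) {
  if (length(mid_d) == 0 || length(mid_t) == 0) return(0L)
  best <- 0L
  recurse <- function(di, used) {
    if (di > length(mid_d)) {
      best <<- max(best, sum(used))
      return()
    }
    recurse(di + 1L, used)  # leave detected di unmatched
    for (tj in seq_along(mid_t)) {
      if (!used[tj] && abs(mid_d[di] - mid_t[tj]) <= tol) {
        used[tj] <- TRUE
        recurse(di + 1L, used)
        used[tj] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(mid_t)))
  best
}

# steady-state amplitude of a filtered pure tone, by least-squares sine
# fit on the middle of a long record (away from edge transients); the
# time-domain measurement is compared against the unit-circle evaluation
# of the designed transfer function
measure_tone_ratio <- function(freq, spec, fs = 1000, dur_s = 30) {
  t <- (0:(dur_s * fs - 1)) / fs
  rec <- recording(sin(2 * pi * freq * t), fs)
  y <- channel_signal(bandpass_filter(rec, spec), 1)
  mid <- seq(round(length(y) * 0.4), round(length(y) * 0.6))
  fit <- lm(y[mid] ~ sin(2 * pi * freq * t[mid]) + cos(2 * pi * freq * t[mid]) - 1)
  sqrt(sum(coef(fit)^2))
}

# small deterministic recording fixture
toy_recording <- function(n = 3000, seed = 42, channels = 2) {
  set.seed(seed)
  recording(matrix(rnorm(n * channels), ncol = channels),
            sampling_rate = 1000,
            baseline_interval = c(0, min(1000, n %/% 2)))
}
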