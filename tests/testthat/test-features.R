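test_that("svd_compress matches closed forms", {
  expect_equal(svd_compress(diag(32)), rep(1, 32))
  # rank-1 outer product: sigma_1 = |u||v|, the rest 0
  u <- c(3, 0, 0, 0); v <- c(0, 2, 0)
  u <- u / sqrt(sum(u^2)) * 3
  set.seed(16)
  u <- rnorm(40); u <- 3 * u / sqrt(sum(u^2))
  v <- rnorm(32); v <- 2 * v / sqrt(sum(v^2))
  s <- svd_compress(u %*% t(v))
  expect_equal(s[1], 6, tolerance = 1e-10)
  expect_lt(max(abs(s[-1])), 1e-10)
})

test_that("singular values match the Gram-matrix eigenvalue oracle", {
  set.seed(17)
  for (rep in 1:10) {
    X <- matrix(rnorm(40 * 32), 40, 32)
    s <- svd_compress(X)
    oracle <- sqrt(pmax(eigen(crossprod(X), symmetric = TRUE)$values, 0))
    expect_equal(s, oracle, tolerance = 1e-9)
    expect_true(all(diff(s) <= 1e-12))  # descending
  }
})

test_that("singular values are invariant to row permutation and rotation", {
  set.seed(18)
  X <- matrix(rnorm(40 * 16), 40, 16)
  s <- svd_compress(X)
  expect_equal(svd_compress(X[sample(40), ]), s, tolerance = 1e-10)
  Q <- qr.Q(qr(matrix(rnorm(16 * 16), 16)))
  expect_equal(svd_compress(X %*% Q), s, tolerance = 1e-9)
  expect_error(svd_compress(matrix(c(1, NA, 2, 3), 2)), "NaN/NA")
  expect_error(svd_compress(matrix(rnorm(6), 2, 3)), "nrow >= ncol")
})

test_that("featurize_segments produces per-channel descending blocks", {
  sim <- simulate_recording(protocol = sim_protocol(rounds = 1), seed = 19)
  filt <- bandpass_filter(sim$recording, filter_spec())
  segs <- extract_segments(filt, sim$events, 1024)
  fz <- featurize_segments(segs)
  expect_equal(dim(fz$features), c(25, 64))
  expect_equal(fz$channel_map, rep(1:2, each = 32))
  expect_equal(as.character(fz$labels), as.character(sim$events$label))
  for (i in 1:5) {
    expect_true(all(diff(fz$features[i, 1:32]) <= 1e-12))
    expect_true(all(diff(fz$features[i, 33:64]) <= 1e-12))
  }
})

test_that("f_value_ranking reproduces the nested-loop oracle on integer toys", {
  feats <- matrix(c(1, 2, 3, 4, 10, 12, 14, 16,
                    5, 5, 6, 6, 1, 1, 2, 2,
                    0, 1, 0, 1, 0, 1, 0, 1), ncol = 3)
  labels <- rep(c("thumb", "index"), each = 4)
  for (conv in c("fisher", "as_printed")) {
    # feature 3 has equal class means: as_printed hits the capped x/0 case
    rk <- suppressWarnings(f_value_ranking(feats, labels, convention = conv))
    oracle <- naive_f_values(feats, labels, convention = conv)
    ord <- rk$feature
    expect_equal(rk$d_within, oracle$d_within[ord], tolerance = 1e-12)
    expect_equal(rk$d_between, oracle$d_between[ord], tolerance = 1e-12)
    expect_equal(rk$f_value, oracle$f[ord], tolerance = 1e-12)
    expect_equal(sort(order(-oracle$f, seq_len(3))), sort(ord))
    expect_equal(ord, order(-oracle$f, seq_len(3)))
  }
})

test_that("degenerate distance ratios follow the documented rules", {
  # constant feature everywhere: F = 0 under both conventions, ranked last
  feats <- cbind(c(1, 2, 3, 4, 7, 8, 9, 10), rep(5, 8))
  labels <- rep(c("thumb", "index"), each = 4)
  rk <- f_value_ranking(feats, labels)
  expect_equal(rk$f_value[rk$feature == 2], 0)
  expect_equal(rk$feature[2], 2)
  # zero within-class spread with distinct means: as_printed 0, fisher capped
  feats2 <- cbind(rep(c(0, 1), each = 4), c(1, 2, 3, 4, 2, 3, 4, 5))
  expect_warning(rk_f <- f_value_ranking(feats2, labels, "fisher"), "capped")
  expect_equal(rk_f$f_value[rk_f$feature == 1], 1e12)
  expect_equal(rk_f$feature[1], 1)  # ranks first under fisher
  rk_p <- f_value_ranking(feats2, labels, "as_printed")
  expect_equal(rk_p$f_value[rk_p$feature == 1], 0)
  # single-sample class is an error
  expect_error(f_value_ranking(feats, c(rep("thumb", 7), "index")),
               "fewer than 2 samples")
})

test_that("F is invariant under positive affine maps of a feature", {
  set.seed(20)
  feats <- matrix(rnorm(60), ncol = 3)
  labels <- rep(c("thumb", "index", "ring", "little"), each = 5)
  base <- f_value_ranking(feats, labels)
  for (rep in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    tf <- feats
    tf[, 2] <- a * tf[, 2] + b
    rk <- f_value_ranking(tf, labels)
    expect_equal(rk$f_value[rk$feature == 2], base$f_value[base$feature == 2],
                 tolerance = 1e-10)
    expect_equal(rk$feature, base$feature)
  }
})

test_that("ranking is invariant to sample order and class relabelling", {
  set.seed(21)
  feats <- matrix(rnorm(100), ncol = 5)
  labels <- rep(gesture_labels()[1:4], each = 5)
  base <- f_value_ranking(feats, labels)
  perm <- sample(20)
  expect_equal(f_value_ranking(feats[perm, ], labels[perm])$feature,
               base$feature)
  relab <- factor(labels, levels = gesture_labels()[1:4],
                  labels = gesture_labels()[c(3, 1, 4, 2)])
  expect_equal(f_value_ranking(feats, relab)$feature, base$feature)
})

test_that("fisher ranking puts a dominant feature first", {
  set.seed(22)
  sim <- simulate_labeled_features(10, 8, informative_k = 1, separation = 10,
                                   seed = 22)
  rk <- f_value_ranking(sim$features, sim$labels, "fisher")
  expect_equal(rk$feature[1], 1)
})

test_that("select_features keeps top-k per channel in channel order", {
  set.seed(23)
  feats <- matrix(rnorm(40 * 8), 40)
  labels <- rep(gesture_labels(), each = 8)
  cmap <- rep(1:2, each = 4)
  rankings <- lapply(1:2, function(ch)
    f_value_ranking(feats[, cmap == ch], labels))
  sel1 <- select_features(rankings, 1, cmap)
  expect_length(sel1, 2)
  expect_equal(sel1[1], rankings[[1]]$feature[1])
  expect_equal(sel1[2], rankings[[2]]$feature[1] + 4L)
  sel_all <- select_features(rankings, 4, cmap)
  expect_setequal(sel_all, 1:8)
  expect_equal(sel_all[1:4], rankings[[1]]$feature)
  expect_error(select_features(rankings, 5, cmap), "1..4")
})
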