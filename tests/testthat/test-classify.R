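test_that("the polynomial kernel matches its closed form and a naive loop", {
  x <- c(1, 1); z <- c(1, 1)
  expect_equal(polynomial_kernel(x, z), 8)  # (<x,z>=2)^3
  expect_equal(polynomial_kernel(c(1, 0), c(0, 1)), 0)
  set.seed(24)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    naive <- 0
    for (i in 1:8) naive <- naive + a[i] * b[i]
    naive <- (1 * naive + 0)^3
    expect_equal(polynomial_kernel(a, b), naive, tolerance = 1e-12)
    expect_equal(polynomial_kernel(a, b, gamma = 0.5, coef0 = 1, degree = 2),
                 (0.5 * sum(a * b) + 1)^2, tolerance = 1e-12)
  }
  expect_error(polynomial_kernel(1:3, 1:4), "equal length")
})

# class means `sep` apart in every dimension, unit within-class SD, so
# separability survives per-feature standardisation
make_clouds <- function(n_per = 10, d = 4, sep = 8, classes = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_per * classes * d), ncol = d)
  y <- factor(rep(gesture_labels()[1:classes], each = n_per),
              levels = gesture_labels()[1:classes])
  x <- x + sep * (as.integer(y) - 1)
  list(x = x, y = y)
}

test_that("all three classifiers separate well-separated clouds perfectly", {
  d <- make_clouds(sep = 10)
  for (kind in c("nbc", "knn", "svm")) {
    m <- train_classifier(d$x, d$y, classifier_spec(kind))
    expect_equal(as.character(predict(m, d$x)), as.character(d$y),
                 info = kind)
  }
})

test_that("KNN with k = 1 reproduces the nearest-label rule", {
  x <- rbind(c(0, 0), c(10, 10), c(0, 10))
  y <- c("thumb", "index", "middle")
  m <- train_classifier(rbind(x, x + 0.01), rep(y, 2),
                        classifier_spec("knn", knn_k = 1))
  expect_equal(as.character(predict(m, x)), y)
  # a query near each training point gets that point's label (Voronoi)
  expect_equal(as.character(predict(m, matrix(c(0.4, -0.2), 1))), "thumb")
})

test_that("NBC matches the equal-variance Bayes midpoint rule", {
  # constructed so empirical means are -1 and +1 with equal variances and
  # priors: the Bayes boundary is exactly 0
  x <- matrix(c(-1.5, -0.5, -1.5, -0.5, 0.5, 1.5, 0.5, 1.5), ncol = 1)
  y <- rep(c("thumb", "index"), each = 4)
  m <- train_classifier(x, y, classifier_spec("nbc"))
  expect_equal(as.character(predict(m, matrix(-0.05))), "thumb")
  expect_equal(as.character(predict(m, matrix(0.05))), "index")
  # exactly at the boundary the posteriors tie; earliest level wins
  expect_equal(as.character(predict(m, matrix(0))), "thumb")
})

test_that("NBC agrees with an independent naive Bayes implementation", {
  d <- make_clouds(n_per = 15, sep = 2.5, classes = 3, seed = 7)
  m <- train_classifier(d$x, d$y, classifier_spec("nbc"))
  ref <- e1071::naiveBayes(d$x, d$y)
  q <- make_clouds(n_per = 15, sep = 2.5, classes = 3, seed = 8)$x
  expect_equal(as.character(predict(m, q)),
               as.character(predict(ref, q)))
})

test_that("NBC floors zero-variance features instead of failing", {
  x <- cbind(c(1, 1, 1, 5, 5, 5), rnorm(6))
  y <- rep(c("thumb", "ring"), each = 3)
  expect_message(m <- train_classifier(x, y, classifier_spec("nbc")),
                 "variance floor")
  expect_equal(as.character(predict(m, matrix(c(1, 0), 1))), "thumb")
})

test_that("KNN vote ties resolve to the earliest class level", {
  # k = 5 with a 2/2 split among the 4 nearest and a far 5th: construct a
  # 1/2/2 neighbourhood where two classes tie at 2 votes
  x <- matrix(c(0, 1, 1.05, 3, 3.05, 10), ncol = 1)
  y <- c("little", "index", "index", "ring", "ring", "little")
  m <- train_classifier(x, y, classifier_spec("knn", knn_k = 5))
  # neighbours of 2: {1, 1.05, 3, 3.05, 0} -> index 2, ring 2, little 1
  expect_equal(as.character(predict(m, matrix(2))), "index")
})

test_that("SVM predictions agree with one-vs-one decision-value voting", {
  d <- make_clouds(n_per = 6, sep = 6, classes = 3, seed = 9)
  spec <- classifier_spec("svm")
  m <- train_classifier(d$x, d$y, spec)
  q <- make_clouds(n_per = 4, sep = 6, classes = 3, seed = 10)$x
  xs <- sweep(sweep(q, 2, m$standardizer$center, "-"), 2,
              m$standardizer$scale, "/")
  pv <- predict(m$model, xs, decision.values = TRUE)
  dv <- attr(pv, "decision.values")
  lv <- m$levels
  votes <- matrix(0, nrow(q), length(lv), dimnames = list(NULL, lv))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/")[[1]]
    win <- ifelse(dv[, cn] > 0, pair[1], pair[2])
    for (i in seq_len(nrow(q))) votes[i, win[i]] <- votes[i, win[i]] + 1
  }
  voted <- lv[apply(votes, 1, which.max)]
  expect_equal(as.character(predict(m, q)), voted)
})

test_that("classifiers are invariant to training sample order", {
  d <- make_clouds(n_per = 8, sep = 3, classes = 4, seed = 11)
  q <- make_clouds(n_per = 5, sep = 3, classes = 4, seed = 12)$x
  set.seed(13)
  perm <- sample(nrow(d$x))
  for (kind in c("nbc", "knn", "svm")) {
    m1 <- train_classifier(d$x, d$y, classifier_spec(kind))
    m2 <- train_classifier(d$x[perm, ], d$y[perm], classifier_spec(kind))
    expect_equal(as.character(predict(m1, q)), as.character(predict(m2, q)),
                 info = kind)
  }
})

test_that("KNN without standardisation is invariant to uniform rescaling", {
  d <- make_clouds(n_per = 8, sep = 3, classes = 3, seed = 14)
  q <- make_clouds(n_per = 5, sep = 3, classes = 3, seed = 15)$x
  spec <- classifier_spec("knn", standardize = FALSE)
  m1 <- train_classifier(d$x, d$y, spec)
  m2 <- train_classifier(d$x * 37, d$y, spec)
  expect_equal(as.character(predict(m1, q)), as.character(predict(m2, q * 37)))
})

test_that("training preconditions are enforced", {
  x <- matrix(rnorm(10), ncol = 2)
  expect_error(train_classifier(x, rep("thumb", 5)), "at least 2 classes")
  expect_error(train_classifier(x, c("thumb", rep("index", 4))),
               "at least 2 training samples")
  d <- make_clouds()
  m <- train_classifier(d$x, d$y, classifier_spec("knn"))
  expect_error(predict(m, matrix(rnorm(6), ncol = 3)), "dimension mismatch")
  expect_error(classifier_spec("knn", knn_k = 4), "odd")
})
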