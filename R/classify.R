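# Classifiers: Gaussian naive Bayes, k-nearest neighbours, and a
# polynomial-kernel SVM (via libSVM through e1071). NBC and KNN are
# implemented here so that tie-breaking is deterministic (earliest class
# level wins) and the NBC variance floor is explicit.

#' Polynomial kernel
#'
#' `G(x, z) = (gamma * <x, z> + coef0)^degree` — the kernel used by the
#' SVM classifier (defaults gamma = 1, coef0 = 0, degree = 3).
#'
#' @param x,z Numeric vectors of equal length.
#' @param gamma,coef0,degree Kernel parameters.
#' @return Scalar kernel value.
#' @export
#' @examples
#' polynomial_kernel(c(1, 1), c(1, 1))  # (2)^3 = 8
polynomial_kernel <- function(x, z, gamma = 1, coef0 = 0, degree = 3) {
  if (length(x) != length(z)) stop_("`x` and `z` must have equal length")
  (gamma * sum(x * z) + coef0)^degree
}

#' Classifier specification
#'
#' @param kind `"nbc"` (Gaussian naive Bayes), `"knn"` (k-nearest
#'   neighbours) or `"svm"` (polynomial-kernel support vector machine).
#' @param knn_k Neighbour count for KNN; odd, default 5.
#' @param cost SVM soft-margin cost C (default 1).
#' @param gamma,coef0,degree Polynomial kernel parameters (defaults 1,
#'   0, 3).
#' @param standardize Z-score features with training statistics before
#'   fitting. Defaults to `TRUE` for KNN and SVM (both are
#'   scale-sensitive) and `FALSE` for NBC (its per-feature Gaussian
#'   likelihood already normalises scale).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("nbc", "knn", "svm"), knn_k = 5L,
                            cost = 1, gamma = 1, coef0 = 0, degree = 3L,
                            standardize = NULL) {
  kind <- match.arg(kind)
  knn_k <- as.integer(knn_k)
  if (knn_k < 1 || knn_k %% 2 == 0) stop_("`knn_k` must be odd and >= 1")
  if (cost <= 0) stop_("`cost` must be positive")
  if (degree < 1) stop_("`degree` must be >= 1")
  if (is.null(standardize)) standardize <- kind %in% c("knn", "svm")
  structure(list(kind = kind, knn_k = knn_k, cost = cost, gamma = gamma,
                 coef0 = coef0, degree = as.integer(degree),
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

#' Train a classifier
#'
#' NBC stores empirical class priors and per-class, per-feature Gaussian
#' mean/variance, with a variance floor of `1e-9` times the pooled
#' feature variance (floored at `1e-12` absolute) so zero-variance
#' features cannot produce degenerate likelihoods. KNN stores the
#' (optionally standardised) training set. SVM fits a one-vs-one
#' multiclass machine with the polynomial kernel via `e1071::svm`
#' (shrinking off, tolerance 1e-3).
#'
#' @param x Numeric feature matrix, one sample per row.
#' @param y Class labels (factor or character), one per row; at least 2
#'   classes with at least 2 samples each.
#' @param spec A [classifier_spec()].
#' @return A model object of class `mmg_classifier`.
#' @export
train_classifier <- function(x, y, spec = classifier_spec()) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  if (nlevels(y) < 2) stop_("need at least 2 classes to train")
  if (any(table(y) < 2)) stop_("every class needs at least 2 training samples")
  if (nrow(x) != length(y)) stop_("feature/label length mismatch")
  st <- if (spec$standardize) standardizer(x) else NULL
  xs <- if (is.null(st)) x else apply_standardizer(x, st)
  model <- switch(spec$kind,
    nbc = {
      pooled_var <- apply(xs, 2, var)
      floor_var <- pmax(1e-9 * pooled_var, 1e-12)
      by_class <- lapply(levels(y), function(cl) {
        xc <- xs[y == cl, , drop = FALSE]
        v <- apply(xc, 2, var)
        floored <- v < floor_var
        if (any(floored))
          message("nbc: variance floor applied to ", sum(floored),
                  " feature(s) in class '", cl, "'")
        list(mean = colMeans(xc), var = pmax(v, floor_var))
      })
      names(by_class) <- levels(y)
      list(priors = as.numeric(table(y)) / length(y), by_class = by_class)
    },
    knn = list(train = xs, y = y, k = spec$knn_k),
    svm = e1071::svm(xs, y, kernel = "polynomial", degree = spec$degree,
                     gamma = spec$gamma, coef0 = spec$coef0,
                     cost = spec$cost, scale = FALSE, shrinking = FALSE,
                     tolerance = 1e-3)
  )
  structure(list(kind = spec$kind, spec = spec, levels = levels(y),
                 standardizer = st, model = model, n_features = ncol(x)),
            class = "mmg_classifier")
}

#' @export
print.mmg_classifier <- function(x, ...) {
  cat(sprintf("<mmg_classifier> %s over %d classes, %d features\n",
              x$kind, length(x$levels), x$n_features))
  invisible(x)
}

#' Predict gesture labels
#'
#' Deterministic decision rules: NBC picks the class with the highest
#' log-posterior; KNN orders neighbours by (distance, training index)
#' and takes a majority vote over the first k; all vote/posterior ties
#' resolve to the earliest class level.
#'
#' @param object A trained `mmg_classifier`.
#' @param newdata Numeric feature matrix (or single vector) with the
#'   training dimensionality.
#' @param ... Unused.
#' @return Factor of predicted labels over the training levels.
#' @export
predict.mmg_classifier <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop_("feature dimension mismatch: model has ", object$n_features,
          ", data has ", ncol(newdata))
  xs <- if (is.null(object$standardizer)) newdata
        else apply_standardizer(newdata, object$standardizer)
  lv <- object$levels
  pred <- switch(object$kind,
    nbc = {
      m <- object$model
      scores <- vapply(seq_along(lv), function(ci) {
        cl <- m$by_class[[ci]]
        log(m$priors[ci]) +
          rowSums(dnorm(xs, mean = matrix(cl$mean, nrow(xs), ncol(xs), byrow = TRUE),
                        sd = matrix(sqrt(cl$var), nrow(xs), ncol(xs), byrow = TRUE),
                        log = TRUE))
      }, numeric(nrow(xs)))
      scores <- matrix(scores, nrow = nrow(xs))
      lv[apply(scores, 1, which.max)]   # which.max: first (earliest level) on ties
    },
    knn = {
      m <- object$model
      apply(xs, 1, function(q) {
        d <- sqrt(colSums((t(m$train) - q)^2))
        nb <- order(d, seq_along(d))[seq_len(m$k)]
        votes <- tabulate(as.integer(m$y[nb]), nbins = length(lv))
        lv[which.max(votes)]
      })
    },
    svm = as.character(predict(object$model, xs))
  )
  factor(pred, levels = lv)
}
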