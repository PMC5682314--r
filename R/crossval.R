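# Cross-validated evaluation. Feature ranking/selection and
# standardisation are re-fitted inside every training fold so the test
# fold never leaks into feature selection.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(labels, folds, seed) {
  labels <- as_class_factor(labels)
  counts <- table(labels)
  short <- names(counts)[counts < folds]
  if (length(short) > 0)
    stop_("class '", short[1], "' has ", counts[short[1]],
          " samples, fewer than folds = ", folds)
  assign_fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign_fold
}

#' Stratified cross-validated evaluation
#'
#' Splits samples into stratified folds; within each training fold,
#' optionally ranks features per channel ([f_value_ranking()]) and keeps
#' the top `k_per_channel`, then trains the classifier and predicts the
#' held-out fold. Identical inputs and seed give an identical report.
#'
#' @param features Numeric matrix, one sample per row.
#' @param labels Class labels, one per row.
#' @param spec A [classifier_spec()].
#' @param folds Fold count (default 5); every class needs at least
#'   `folds` samples.
#' @param seed Integer seed for the fold assignment.
#' @param k_per_channel If non-`NULL`, per-channel feature selection is
#'   performed inside each training fold, keeping this many features per
#'   channel.
#' @param channel_map Column-to-channel assignment, required when
#'   `k_per_channel` is given.
#' @param ranking_convention Passed to [f_value_ranking()].
#' @return An `evaluation_report`: confusion matrix (rows = truth),
#'   overall/per-class/per-fold accuracy, per-fold selected feature
#'   indices, and the evaluation parameters.
#' @export
cross_validate <- function(features, labels, spec = classifier_spec(),
                           folds = 5L, seed = 1L, k_per_channel = NULL,
                           channel_map = NULL,
                           ranking_convention = "fisher") {
  features <- as.matrix(features)
  labels <- as_class_factor(labels)
  if (nlevels(labels) < 2) stop_("need at least 2 classes to evaluate")
  if (!is.null(k_per_channel) && is.null(channel_map))
    stop_("`channel_map` is required for per-channel feature selection")
  fold_of <- stratified_folds(labels, folds, seed)
  lv <- levels(labels)
  confusion <- matrix(0L, nlevels(labels), nlevels(labels),
                      dimnames = list(truth = lv, predicted = lv))
  fold_acc <- numeric(folds)
  selected <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    xtr <- features[tr, , drop = FALSE]; ytr <- labels[tr]
    xte <- features[te, , drop = FALSE]; yte <- labels[te]
    if (!is.null(k_per_channel)) {
      rankings <- lapply(sort(unique(channel_map)), function(ch)
        f_value_ranking(xtr[, channel_map == ch, drop = FALSE], ytr,
                        convention = ranking_convention))
      sel <- select_features(rankings, k_per_channel, channel_map)
      xtr <- xtr[, sel, drop = FALSE]
      xte <- xte[, sel, drop = FALSE]
      selected[[f]] <- sel
    }
    model <- train_classifier(xtr, ytr, spec)
    pred <- predict(model, xte)
    confusion <- confusion + table(factor(yte, lv), factor(pred, lv))
    fold_acc[f] <- mean(pred == yte)
  }
  total <- sum(confusion)
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / total,
                 per_class_accuracy = per_class,
                 fold_accuracy = fold_acc,
                 selected_features = selected,
                 classifier = spec$kind, folds = folds, seed = seed,
                 k_per_channel = k_per_channel,
                 ranking_convention = if (is.null(k_per_channel)) NULL
                                      else ranking_convention,
                 n_samples = total),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d-fold CV on %d samples\n",
              x$classifier, x$folds, x$n_samples))
  cat(sprintf("  accuracy: %.3f (folds: %s)\n", x$accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  if (!is.null(x$fder)) cat(sprintf("  FDER: %s\n", format(x$fder)))
  print(x$confusion)
  invisible(x)
}

#' Accuracy as a function of the number of selected features
#'
#' Re-runs [cross_validate()] for every feature count in `k_values` and
#' every classifier kind, with per-fold feature ranking.
#'
#' @param features,labels,folds,seed,channel_map,ranking_convention As
#'   in [cross_validate()].
#' @param specs List of [classifier_spec()]s to sweep (default: nbc,
#'   knn, svm with default parameters).
#' @param k_values Feature counts per channel to evaluate.
#' @return A `data.frame` with columns `classifier`, `k`, `accuracy`.
#' @export
sweep_feature_count <- function(features, labels,
                                specs = list(classifier_spec("nbc"),
                                             classifier_spec("knn"),
                                             classifier_spec("svm")),
                                k_values = 1:32, folds = 5L, seed = 1L,
                                channel_map = NULL,
                                ranking_convention = "fisher") {
  rows <- lapply(specs, function(sp) {
    acc <- vapply(k_values, function(k)
      cross_validate(features, labels, sp, folds = folds, seed = seed,
                     k_per_channel = k, channel_map = channel_map,
                     ranking_convention = ranking_convention)$accuracy,
      numeric(1))
    data.frame(classifier = sp$kind, k = k_values, accuracy = acc)
  })
  do.call(rbind, rows)
}
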