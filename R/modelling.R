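# Class-balanced tenfold cross-validation with in-fold rank-sum feature
# selection and two classifiers (random forest, Gaussian process),
# producing one out-of-fold probability per sample.
#
# The critical design point is leakage control: within every fold the
# discriminative features are re-selected on the 90% training split alone,
# and only those features are carried to the 10% test split. Selecting
# once on the full data before splitting looks innocuous but, with many
# features and few samples, inflates apparent AUC dramatically;
# `run_cv_leaky()` implements that broken variant purely as a negative
# control so the effect can be demonstrated.

#' Model configuration for cross-validated classification
#'
#' @param classifier `"random_forest"` or `"gaussian_process"`.
#' @param n_folds Number of cross-validation folds (default 10: each fold
#'   trains on 90% and tests on the held-out 10%).
#' @param n_features Number of lowest-p rank-sum features carried into the
#'   classifier per fold (default 100).
#' @param seed Integer seed; expands deterministically into sub-seeds for
#'   fold shuffling and per-fold classifier training.
#' @param ntree Random-forest tree count (default 1000; feature subsampling
#'   is the usual square root of the feature count).
#' @param gp_length_scale Radial-basis-function kernel length scale for the
#'   Gaussian process, on standardised features. `NULL` (default) uses the
#'   median pairwise training distance heuristic, computed per fold.
#' @return An object of class `model_config`.
#' @export
model_config <- function(classifier = c("random_forest", "gaussian_process"),
                         n_folds = 10L, n_features = 100L, seed = 1L,
                         ntree = 1000L, gp_length_scale = NULL) {
  if (!is.character(classifier) ||
      !all(classifier %in% c("random_forest", "gaussian_process"))) {
    stop_config(sprintf("unknown classifier '%s'",
                        paste(setdiff(classifier, c("random_forest", "gaussian_process")),
                              collapse = ", ")))
  }
  classifier <- classifier[1]
  if (!is_count(n_folds, 2L)) stop_config("n_folds must be an integer >= 2")
  if (!is_count(n_features, 1L)) stop_config("n_features must be an integer >= 1")
  if (!is_count(ntree, 1L)) stop_config("ntree must be a positive integer")
  if (!is.null(gp_length_scale) &&
      (!is_number(gp_length_scale) || gp_length_scale <= 0)) {
    stop_config("gp_length_scale must be NULL or a positive number")
  }
  structure(list(classifier = classifier, n_folds = as.integer(n_folds),
                 n_features = as.integer(n_features), seed = as.integer(seed),
                 ntree = as.integer(ntree), gp_length_scale = gp_length_scale),
            class = "model_config")
}

#' Balance classes by random undersampling of the majority class
#'
#' The minority class is kept in full; the majority class is reduced to the
#' same size by uniform random subsampling without replacement. Original
#' sample order is preserved among the retained samples, and the result is
#' deterministic given `seed`.
#'
#' @param fm A `voc_features` matrix (see [build_feature_matrix()]).
#' @param seed Integer seed for the subsample draw.
#' @return A balanced `voc_features`.
#' @export
balance_classes <- function(fm, seed) {
  n1 <- sum(fm$labels == 1); n0 <- sum(fm$labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop_degenerate("both classes must be present to balance")
  }
  if (n1 == n0) return(fm)
  n_min <- min(n1, n0)
  maj <- if (n1 > n0) 1L else 0L
  idx_maj <- which(fm$labels == maj)
  keep_maj <- with_seed(seed, sample(idx_maj, n_min))
  keep <- sort(c(which(fm$labels != maj), keep_maj))
  fm_subset(fm, keep)
}

#' Select the k most discriminative features by rank-sum p-value
#'
#' Features are ranked by two-sided Mann-Whitney p-value comparing positive
#' vs negative training samples. Ties in p are broken by larger absolute
#' rank-biserial effect, then by lower feature index. Features constant
#' across all training samples are assigned p = 1 and so rank last.
#'
#' @param train_values Training samples x features matrix.
#' @param train_labels Binary labels for the training samples.
#' @param k Number of features to return.
#' @return Integer vector of `k` feature column indices, best first.
#' @export
ranksum_select <- function(train_values, train_labels, k) {
  train_labels <- check_binary_labels(train_labels)
  if (!any(train_labels == 1) || !any(train_labels == 0)) {
    stop_degenerate("both classes must be present in the training labels")
  }
  if (!is_count(k, 1L) || k > ncol(train_values)) {
    stop_argument(sprintf("k must be an integer in 1..%d", ncol(train_values)))
  }
  st <- ranksum_feature_stats(train_values, train_labels)
  ord <- order(st$p, -abs(st$effect), seq_along(st$p))
  ord[seq_len(k)]
}

#' Train a classifier on selected features
#'
#' @param train_values Training matrix restricted to the fold's selected
#'   features.
#' @param train_labels Binary labels.
#' @param config A [model_config()].
#' @param seed Training seed (defaults to `config$seed`).
#' @return A fitted-classifier handle usable with [predict_proba()].
#' @export
train_classifier <- function(train_values, train_labels, config,
                             seed = config$seed) {
  train_labels <- check_binary_labels(train_labels)
  if (!any(train_labels == 1) || !any(train_labels == 0)) {
    stop_degenerate("both classes must be present for training")
  }
  train_values <- as.matrix(train_values)
  y <- factor(train_labels, levels = c(0, 1))
  if (config$classifier == "random_forest") {
    model <- with_seed(seed, randomForest::randomForest(
      x = train_values, y = y, ntree = config$ntree,
      mtry = max(1L, floor(sqrt(ncol(train_values))))))
    handle <- list(classifier = "random_forest", model = model,
                   n_features = ncol(train_values))
  } else {
    # Standardise on training statistics; the same transform is replayed on
    # test samples. Constant features get unit scale.
    center <- colMeans(train_values)
    scale <- apply(train_values, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    Z <- sweep(sweep(train_values, 2, center), 2, scale, "/")
    ls <- config$gp_length_scale
    if (is.null(ls)) {
      d <- stats::dist(Z)
      ls <- stats::median(d[d > 0])
      if (!is.finite(ls) || ls <= 0) ls <- 1
    }
    # Least-squares GP classification: regress the 0/1 labels under an RBF
    # kernel and clip the posterior mean to [0, 1]. Deterministic, and the
    # scores separate much better on small folds than the logistic-link
    # Laplace approximation, whose probabilities are heavily shrunk toward
    # 0.5 at these sample sizes.
    model <- with_seed(seed, kernlab::gausspr(
      x = Z, y = as.numeric(train_labels), kernel = "rbfdot",
      kpar = list(sigma = 1 / (2 * ls^2)), var = 0.1))
    handle <- list(classifier = "gaussian_process", model = model,
                   center = center, scale = scale, length_scale = ls,
                   n_features = ncol(train_values))
  }
  structure(handle, class = "voc_classifier")
}

#' Predict positive-class probabilities
#'
#' @param handle A fitted classifier from [train_classifier()].
#' @param test_values Matrix restricted to the same selected features, in
#'   the same order, as used for training.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(handle, test_values) {
  if (!inherits(handle, "voc_classifier")) stop_argument("not a voc_classifier")
  test_values <- as.matrix(test_values)
  if (ncol(test_values) != handle$n_features) {
    stop_argument(sprintf("test matrix has %d features but training used %d",
                          ncol(test_values), handle$n_features))
  }
  if (handle$classifier == "random_forest") {
    p <- stats::predict(handle$model, test_values, type = "prob")[, "1"]
  } else {
    Z <- sweep(sweep(test_values, 2, handle$center), 2, handle$scale, "/")
    p <- as.numeric(kernlab::predict(handle$model, Z))
  }
  p <- as.numeric(p)
  pmin(1, pmax(0, p))
}

# Stratified fold assignment: each class is shuffled and dealt round-robin
# across folds, so class proportions are preserved up to remainder.
make_folds <- function(labels, n_folds, seed) {
  labels <- check_binary_labels(labels)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < n_folds)) {
    stop_config(sprintf(
      paste0("each class needs at least n_folds samples for stratified CV ",
             "(have %d negative / %d positive, n_folds = %d); ",
             "use a smaller n_folds"),
      counts[1], counts[2], n_folds))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Run class-stratified cross-validation with in-fold feature selection
#'
#' Samples are partitioned into `n_folds` stratified folds. For every fold,
#' rank-sum feature selection is performed on the training split only, the
#' classifier is trained on the selected training features, and
#' probabilities are produced for the held-out split; after all folds each
#' sample has exactly one out-of-fold probability. Fully deterministic
#' given `config$seed`.
#'
#' The input is expected to be class-balanced (see [balance_classes()]);
#' the function itself only requires both classes to have at least
#' `n_folds` samples.
#'
#' @param fm A `voc_features` matrix.
#' @param config A [model_config()].
#' @return An object of class `voc_cv`: list with `sample_ids`, `labels`,
#'   `probabilities`, `fold_of`, `selected_features` (per-fold index
#'   lists) and `config`.
#' @export
run_cv <- function(fm, config) {
  seeds <- derive_seeds(config$seed, config$n_folds + 1L)
  fold_of <- make_folds(fm$labels, config$n_folds, seeds[1])
  k <- min(config$n_features, ncol(fm$values))
  prob <- rep(NA_real_, length(fm$labels))
  selected <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    sel <- ranksum_select(fm$values[train, , drop = FALSE], fm$labels[train], k)
    handle <- train_classifier(fm$values[train, sel, drop = FALSE],
                               fm$labels[train], config, seed = seeds[f + 1L])
    prob[test] <- predict_proba(handle, fm$values[test, sel, drop = FALSE])
    selected[[f]] <- sel
  }
  structure(list(sample_ids = fm$sample_ids, labels = fm$labels,
                 probabilities = prob, fold_of = fold_of,
                 selected_features = selected, config = config),
            class = "voc_cv")
}

#' Cross-validation with leaky whole-dataset feature selection
#'
#' Negative control only: features are selected once on the *full* data
#' (training and test folds together) before cross-validation, which leaks
#' test-label information into the feature set. On null data with many
#' features and few samples this inflates apparent AUC well above chance;
#' compare against [run_cv()] to demonstrate why in-fold selection is
#' required. Never use this variant for real inference.
#'
#' @inheritParams run_cv
#' @return A `voc_cv`, as from [run_cv()].
#' @export
run_cv_leaky <- function(fm, config) {
  seeds <- derive_seeds(config$seed, config$n_folds + 1L)
  fold_of <- make_folds(fm$labels, config$n_folds, seeds[1])
  k <- min(config$n_features, ncol(fm$values))
  sel <- ranksum_select(fm$values, fm$labels, k)  # the leak: all samples
  prob <- rep(NA_real_, length(fm$labels))
  for (f in seq_len(config$n_folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    handle <- train_classifier(fm$values[train, sel, drop = FALSE],
                               fm$labels[train], config, seed = seeds[f + 1L])
    prob[test] <- predict_proba(handle, fm$values[test, sel, drop = FALSE])
  }
  structure(list(sample_ids = fm$sample_ids, labels = fm$labels,
                 probabilities = prob, fold_of = fold_of,
                 selected_features = replicate(config$n_folds, sel,
                                               simplify = FALSE),
                 config = config),
            class = "voc_cv")
}

#' @export
print.voc_cv <- function(x, ...) {
  cat(sprintf("<voc_cv> %s, %d samples, %d folds\n",
              x$config$classifier, length(x$labels), x$config$n_folds))
  invisible(x)
}
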