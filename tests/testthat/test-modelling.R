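# Balancing, rank-sum selection, classifiers and cross-validation.

fm_from_matrix <- function(X, labels) {
  spectra <- lapply(seq_len(nrow(X)), function(i) {
    ims_spectrum(sprintf("s%02d", i), seq_len(1), seq_len(ncol(X)),
                 matrix(X[i, ], 1))
  })
  build_feature_matrix(spectra, labels,
                       preprocess_config(crop_window(0, 1, 0, ncol(X)), 0))
}

test_that("balancing subsamples the majority class to the minority size", {
  set.seed(1)
  X <- matrix(rnorm(196 * 5), 196, 5)
  labels <- c(rep(1, 39), rep(0, 157))
  fm <- fm_from_matrix(X, labels)
  bal <- balance_classes(fm, seed = 42)
  expect_equal(sum(bal$labels == 1), 39)
  expect_equal(sum(bal$labels == 0), 39)
  # minority retained in full
  expect_true(all(fm$sample_ids[fm$labels == 1] %in% bal$sample_ids))
  # deterministic given seed, different across seeds
  expect_identical(balance_classes(fm, seed = 42)$sample_ids, bal$sample_ids)
  expect_false(identical(balance_classes(fm, seed = 43)$sample_ids,
                         bal$sample_ids))
  # retained samples keep their original relative order
  expect_identical(bal$sample_ids,
                   fm$sample_ids[sort(match(bal$sample_ids, fm$sample_ids))])

  balanced <- fm_from_matrix(X[1:10, ], rep(c(1, 0), each = 5))
  expect_identical(balance_classes(balanced, 1), balanced)
  oneclass <- fm_from_matrix(X[1:3, ], rep(1, 3))
  expect_error(balance_classes(oneclass, 1), class = "voc_degenerate_error")
})

test_that("rank-sum selection matches the exact enumeration oracle", {
  # complete separation at 3 vs 3 has exact two-sided p = 0.1
  expect_equal(mw_test(c(4, 5, 6), c(1, 2, 3))$p, 0.1)
  set.seed(21)
  for (i in 1:8) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:4, n1, replace = TRUE)  # ties on purpose
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(mw_test(x, y)$p, oracle_mw_p(x, y), tolerance = 1e-12)
  }
  # large-sample path agrees with the standard implementation
  for (i in 1:5) {
    x <- rnorm(15 + i); y <- rnorm(20) + 0.3
    expect_equal(mw_test(x, y)$p,
                 stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("feature selection ranks by p, breaks ties by effect, flags constants", {
  X <- cbind(sep = c(1, 2, 3, 4, 5, 6),       # complete separation, p = 0.1
             weak = c(2, 1, 3, 2, 4, 3),
             const = rep(7, 6),
             anti = c(6, 5, 4, 3, 2, 1))      # also p = 0.1, |effect| = 1
  labels <- c(0, 0, 0, 1, 1, 1)
  sel <- ranksum_select(X, labels, 4)
  # both separated features precede the weak one; the constant is last
  expect_true(all(match(c(1, 4), sel) < match(2, sel)))
  expect_equal(sel[4], 3)
  # tie between features 1 and 4 (equal p, equal |effect|) -> lower index first
  expect_equal(sel[1:2], c(1, 4))
  st <- vocptb:::ranksum_feature_stats(X, labels)
  expect_equal(st$p[3], 1)
  expect_equal(st$effect[3], 0)
  expect_equal(st$effect[1], 1)   # rank-biserial for complete separation
  expect_equal(st$effect[4], -1)

  expect_error(ranksum_select(X, labels, 5), class = "voc_argument_error")
  expect_error(ranksum_select(X, rep(1, 6), 2), class = "voc_degenerate_error")
})

test_that("vectorised selection statistics agree with the scalar test", {
  set.seed(31)
  # exact path (6 vs 6) and normal path (12 vs 13), with heavy ties
  for (ns in list(c(6, 6), c(12, 13))) {
    labels <- rep(c(1, 0), times = ns)
    X <- matrix(sample(0:3, sum(ns) * 40, replace = TRUE), sum(ns), 40)
    st <- vocptb:::ranksum_feature_stats(X, labels)
    ref <- vapply(seq_len(ncol(X)), function(j) {
      mw_test(X[labels == 1, j], X[labels == 0, j])$p
    }, numeric(1))
    ref[apply(X, 2, function(v) length(unique(v)) == 1)] <- 1
    expect_equal(st$p, ref, tolerance = 1e-10)
  }
})

test_that("classifiers separate a trivial problem and are deterministic", {
  X <- matrix(c(rep(0, 5), rep(10, 5)), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  for (cl in c("random_forest", "gaussian_process")) {
    h <- train_classifier(X, y, model_config(cl, seed = 3))
    p <- predict_proba(h, X)
    expect_true(all(p[y == 1] >= 0.9), label = cl)
    expect_true(all(p[y == 0] <= 0.1), label = cl)
    expect_true(all(p >= 0 & p <= 1))
    h2 <- train_classifier(X, y, model_config(cl, seed = 3))
    expect_identical(predict_proba(h2, X), p)
    # single-sample prediction works
    expect_length(predict_proba(h, X[1, , drop = FALSE]), 1L)
    # wrong width is refused
    expect_error(predict_proba(h, cbind(X, X)), class = "voc_argument_error")
  }
  expect_error(model_config("svm"), class = "voc_config_error")
  expect_error(train_classifier(X, rep(1, 10), model_config("random_forest")),
               class = "voc_degenerate_error")
})

test_that("cross-validation partitions every sample into exactly one test fold", {
  set.seed(4)
  X <- matrix(rnorm(20 * 30), 20, 30)
  fm <- fm_from_matrix(X, rep(c(0, 1), 10))
  cfg <- model_config("random_forest", n_folds = 10, n_features = 5,
                      ntree = 50, seed = 2)
  cv <- run_cv(fm, cfg)
  expect_equal(sort(unique(cv$fold_of)), 1:10)
  expect_equal(tabulate(cv$fold_of, 10), rep(2L, 10))  # stratified 1+1 per fold
  expect_true(all(!is.na(cv$probabilities)))
  expect_true(all(cv$probabilities >= 0 & cv$probabilities <= 1))
  expect_length(cv$selected_features, 10L)
  expect_true(all(lengths(cv$selected_features) == 5L))
  # per-fold class balance is preserved
  for (f in 1:10) expect_equal(sum(fm$labels[cv$fold_of == f]), 1L)
  # determinism
  cv2 <- run_cv(fm, cfg)
  expect_identical(cv2, cv)
  # too few samples per class for the fold count
  small <- fm_from_matrix(X[1:8, ], rep(c(0, 1), 4))
  expect_error(run_cv(small, cfg), class = "voc_config_error",
               regexp = "smaller n_folds")
})

test_that("whole-dataset feature selection leaks: inflated AUC on null data", {
  # 2000 noise features, 60 samples; the in-fold pipeline stays near
  # chance while pre-selected features score far above it.
  gaps <- vapply(1:3, function(s) leakage_experiment(seed = s), numeric(2))
  expect_gte(mean(gaps["leaky", ]), 0.7)
  expect_true(all(gaps["infold", ] > 0.25 & gaps["infold", ] < 0.75))
  expect_gte(mean(gaps["leaky", ]) - mean(gaps["infold", ]), 0.2)
})
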