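# Crop, threshold and feature-matrix construction.

test_that("cropping returns the expected sub-matrix and errors out of bounds", {
  set.seed(3)
  m <- matrix(rnorm(100), 10, 10)
  sp <- make_spec(m)
  full <- crop_spectrum(sp, crop_window(0, 10, 0, 10))
  expect_identical(full$intensities, m)
  sub <- crop_spectrum(sp, crop_window(2, 6, 3, 8))
  expect_equal(dim(sub$intensities), c(4L, 5L))
  expect_equal(sub$intensities[1, 1], m[3, 4])
  expect_equal(sub$retention, sp$retention[3:6])
  expect_error(crop_spectrum(sp, crop_window(5, 12, 0, 10)),
               class = "voc_bounds_error")
  expect_error(crop_window(3, 3, 0, 2), class = "voc_argument_error")
})

test_that("thresholding zeroes strictly-below cells and keeps the rest", {
  sp <- make_spec(matrix(c(5, 0, 1, 9), 2, 2, byrow = TRUE))
  th <- apply_threshold(sp, 2)
  expect_equal(th$intensities, matrix(c(5, 0, 0, 9), 2, 2, byrow = TRUE))
  # threshold equal to a cell keeps it (>= survives)
  expect_equal(apply_threshold(sp, 5)$intensities[1, 1], 5)
  expect_identical(apply_threshold(sp, 0)$intensities, sp$intensities)
  expect_true(all(apply_threshold(sp, 10)$intensities == 0))
  expect_error(apply_threshold(sp, -1), class = "voc_argument_error")
})

test_that("crop and threshold commute, and non-zeros decrease in threshold", {
  set.seed(5)
  for (i in 1:5) {
    sp <- make_spec(matrix(rexp(48), 6, 8))
    w <- crop_window(1, 5, 2, 7)
    t <- runif(1, 0, 2)
    a <- apply_threshold(crop_spectrum(sp, w), t)
    b <- crop_spectrum(apply_threshold(sp, t), w)
    expect_equal(a$intensities, b$intensities)
    nz <- vapply(c(0, 0.5, 1, 2, 5),
                 function(t) sum(apply_threshold(sp, t)$intensities != 0),
                 numeric(1))
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("suggested crop matches the exhaustive minimal window at full coverage", {
  # single support point
  m <- matrix(0, 10, 10); m[5, 8] <- 3  # 0-based cell (4, 7)
  w <- suggest_crop_window(list(make_spec(m)), threshold = 1, coverage = 1)
  expect_equal(unclass(w)[c("retention_lo", "retention_hi", "drift_lo", "drift_hi")],
               list(retention_lo = 4L, retention_hi = 5L, drift_lo = 7L, drift_hi = 8L))
  # two spectra, support at (1,1) and (6,3): bounding box rows [1,7) cols [1,4)
  m1 <- matrix(0, 8, 8); m1[2, 2] <- 5
  m2 <- matrix(0, 8, 8); m2[7, 4] <- 5
  w2 <- suggest_crop_window(list(make_spec(m1), make_spec(m2)), 1, 1)
  expect_equal(c(w2$retention_lo, w2$retention_hi, w2$drift_lo, w2$drift_hi),
               c(1L, 7L, 1L, 4L))
  oracle <- oracle_crop_window(list(make_spec(m1), make_spec(m2)), 1, 1)
  expect_equal(c(w2$retention_lo, w2$retention_hi, w2$drift_lo, w2$drift_hi),
               as.integer(oracle))
  # random sparse cases: greedy must equal the exhaustive bounding box
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(0, 7, 7)
    m[sample(49, 4)] <- runif(4, 1, 5)
    w <- suggest_crop_window(list(make_spec(m)), 0.5, 1)
    o <- oracle_crop_window(list(make_spec(m)), 0.5, 1)
    expect_equal(c(w$retention_lo, w$retention_hi, w$drift_lo, w$drift_hi),
                 as.integer(o))
  }
  expect_error(suggest_crop_window(list(make_spec(matrix(0, 4, 4))), 1, 1),
               class = "voc_degenerate_error")
})

test_that("partial coverage windows retain the requested mass", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rexp(64), 8, 8)
    sp <- make_spec(m)
    w <- suggest_crop_window(list(sp), 0.5, coverage = 0.8)
    mt <- m; mt[mt < 0.5] <- 0
    inside <- sum(mt[(w$retention_lo + 1):w$retention_hi,
                     (w$drift_lo + 1):w$drift_hi])
    expect_gte(inside, 0.8 * sum(mt) - 1e-12)
  }
})

test_that("feature matrix flattens row-major with shared feature index", {
  m1 <- matrix(1:4, 2, 2, byrow = TRUE)  # rows (1,2),(3,4)
  m2 <- matrix(5:8, 2, 2, byrow = TRUE)
  cfg <- preprocess_config(crop_window(0, 2, 0, 2), 0)
  fm <- build_feature_matrix(list(make_spec(m1, "a"), make_spec(m2, "b")),
                             c(0, 1), cfg)
  expect_equal(dim(fm$values), c(2L, 4L))
  expect_equal(unname(fm$values[1, ]), c(1, 2, 3, 4))  # drift varies fastest
  expect_equal(unname(fm$values[2, ]), c(5, 6, 7, 8))
  expect_equal(fm$feature_index$retention_idx, c(0L, 0L, 1L, 1L))
  expect_equal(fm$feature_index$drift_idx, c(0L, 1L, 0L, 1L))

  # 1x1 crop keeps a single (thresholded) cell
  fm1 <- build_feature_matrix(list(make_spec(m1, "a")), 1,
                              preprocess_config(crop_window(1, 2, 0, 1), 2))
  expect_equal(dim(fm1$values), c(1L, 1L))
  expect_equal(unname(fm1$values[1, 1]), 3)

  # sample entirely below threshold keeps an all-zero row
  lo <- make_spec(matrix(0.1, 2, 2), "lo")
  fm0 <- build_feature_matrix(list(make_spec(m1, "a"), lo), c(1, 0),
                              preprocess_config(crop_window(0, 2, 0, 2), 0.5))
  expect_equal(unname(fm0$values[2, ]), rep(0, 4))
  expect_equal(length(fm0$sample_ids), 2L)

  expect_error(build_feature_matrix(list(make_spec(m1)), c(0, 1), cfg),
               class = "voc_argument_error")
  other <- ims_spectrum("c", c(1, 3), c(1, 2), m1)
  expect_error(build_feature_matrix(list(make_spec(m1), other), c(0, 1), cfg),
               class = "voc_argument_error")
})

test_that("the reported reduction factor is raw over retained non-zeros", {
  m <- matrix(c(10, 3, 0.2, 0,
                8, 0.1, 0.3, 0.4), 2, 4, byrow = TRUE)
  # raw non-zeros: 7; after crop to all cols + threshold 1: cells 10, 3, 8 -> 3
  fm <- build_feature_matrix(list(make_spec(m)), 1,
                             preprocess_config(crop_window(0, 2, 0, 4), 1))
  expect_equal(fm$reduction_factor, 7 / 3)
  expect_message(
    build_feature_matrix(list(make_spec(m)), 1,
                         preprocess_config(crop_window(0, 2, 0, 4), 1),
                         verbose = TRUE),
    "reduction factor")
})
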