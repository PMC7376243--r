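# ROC/AUC, confidence intervals, thresholds and between-group testing.

test_that("ROC curves hit the canonical corner cases", {
  perfect <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  flat <- roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(flat), 2L)
  expect_equal(flat$fpr, c(0, 1)); expect_equal(flat$tpr, c(0, 1))
  anti <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(0, 0, 1, 1))
  expect_true(any(anti$fpr == 1 & anti$tpr == 0))
  set.seed(12)
  rc <- roc_curve(runif(30), rbinom(30, 1, 0.5))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_equal(unlist(rc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_error(roc_curve(runif(4), rep(1, 4)), class = "voc_degenerate_error")
})

test_that("AUC equals brute-force pair counting and trapezoidal ROC area", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0))$auc, 0.5)
  set.seed(14)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    prob <- round(runif(n), 2)  # duplicates -> tied pairs exercised
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    a <- auc(prob, labels)$auc
    expect_equal(a, oracle_auc(prob, labels), tolerance = 1e-12)
    expect_equal(a, trapezoid_auc(roc_curve(prob, labels)), tolerance = 1e-12)
    # complement symmetry
    expect_equal(a + auc(prob, 1 - labels)$auc, 1, tolerance = 1e-12)
  }
})

test_that("AUC, ROC shape and group p are invariant to monotone transforms", {
  set.seed(15)
  prob <- runif(40); labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  tr <- function(p) stats::plogis(3 * p - 1)   # strictly increasing
  expect_equal(auc(tr(prob), labels)$auc, auc(prob, labels)$auc)
  expect_equal(group_pvalue(tr(prob), labels), group_pvalue(prob, labels))
  r1 <- roc_curve(prob, labels); r2 <- roc_curve(tr(prob), labels)
  expect_equal(r2[c("fpr", "tpr")], r1[c("fpr", "tpr")])
})

test_that("DeLong interval matches pROC and bootstrap brackets the point", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (i in 1:5) {
    prob <- runif(50); labels <- rbinom(50, 1, 0.4); labels[1:2] <- c(0, 1)
    mine <- auc(prob, labels)
    ref <- suppressMessages(
      as.numeric(pROC::ci.auc(pROC::roc(labels, prob, quiet = TRUE,
                                        direction = "<", levels = c(0, 1)),
                              method = "delong")))
    expect_equal(mine$auc, ref[2], tolerance = 1e-10)
    expect_equal(max(0, ref[1]), mine$ci_lower, tolerance = 1e-10)
    expect_equal(min(1, ref[3]), mine$ci_upper, tolerance = 1e-10)
  }
  bs <- auc(runif(40), rbinom(40, 1, 0.5) | c(1, rep(0, 39)),
            ci_method = "bootstrap", n_boot = 200, seed = 7)
  expect_true(bs$ci_lower <= bs$auc && bs$auc <= bs$ci_upper)
  expect_true(bs$ci_lower >= 0 && bs$ci_upper <= 1)
})

test_that("Youden threshold maximises J with ties toward specificity", {
  th <- choose_threshold(c(0.9, 0.6, 0.4, 0.1), c(1, 1, 0, 0))
  expect_true(th > 0.4 && th <= 0.6)
  # all identical probabilities: degenerate threshold, J = 0
  thd <- choose_threshold(rep(0.3, 4), c(1, 0, 1, 0))
  expect_equal(thd, 0.3)
  cs <- suppressWarnings(confusion_stats(rep(0.3, 4), c(1, 0, 1, 0), thd))
  expect_equal(cs$sensitivity + cs$specificity - 1, 0)
  expect_equal(choose_threshold(runif(6), c(1, 0, 1, 0, 1, 0),
                                policy = "fixed"), 0.5)
})

test_that("confusion statistics recover the textbook arithmetic with exact CIs", {
  # TP 9, FP 1, TN 9, FN 3 at threshold 0.5
  prob <- c(rep(0.8, 9), rep(0.2, 3), rep(0.7, 1), rep(0.1, 9))
  labels <- c(rep(1, 12), rep(0, 10))
  cs <- confusion_stats(prob, labels, 0.5)
  expect_equal(cs[c("tp", "fp", "tn", "fn")], list(tp = 9L, fp = 1L, tn = 9L, fn = 3L))
  expect_equal(cs$sensitivity, 0.75)
  expect_equal(cs$specificity, 0.90)
  expect_equal(cs$ppv, 0.9)
  expect_equal(cs$npv, 0.75)

  # exact CI agrees with direct binomial-tail inversion (sens 13/22)
  for (case in list(c(13, 22), c(0, 10), c(10, 10), c(350, 1000))) {
    expect_equal(clopper_pearson(case[1], case[2]),
                 oracle_clopper_pearson(case[1], case[2]), tolerance = 1e-9)
  }
  # interval contains the empirical rate and shrinks with n
  widths <- vapply(c(10, 100, 1000), function(n) {
    x <- round(0.6 * n)
    ci <- clopper_pearson(x, n)
    expect_true(ci[1] <= x / n && x / n <= ci[2])
    diff(ci)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # degenerate: everything predicted positive
  expect_warning(cs2 <- confusion_stats(c(0.9, 0.8, 0.7), c(1, 1, 0), 0.1),
                 "npv")
  expect_equal(cs2$specificity, 0)
  expect_true(is.nan(cs2$npv))
})

test_that("between-group p-value follows the rank-sum test", {
  expect_equal(group_pvalue(c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3),
                            c(1, 1, 1, 0, 0, 0)), 0.1)
  expect_equal(group_pvalue(rep(0.4, 8), rep(c(1, 0), 4)), 1)
  # null uniformity sanity: p-values not concentrated anywhere
  set.seed(18)
  ps <- vapply(1:120, function(i) {
    group_pvalue(runif(40), rep(c(1, 0), each = 20))
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("the assembled performance report is internally consistent", {
  set.seed(19)
  prob <- c(runif(30, 0.3, 1), runif(30, 0, 0.7))
  labels <- rep(c(1, 0), each = 30)
  perf <- performance_report(prob, labels)
  expect_s3_class(perf, "voc_performance")
  expect_equal(perf$sensitivity, perf$tp / (perf$tp + perf$fn))
  expect_equal(perf$specificity, perf$tn / (perf$tn + perf$fp))
  expect_equal(perf$ppv, perf$tp / (perf$tp + perf$fp))
  expect_equal(perf$npv, perf$tn / (perf$tn + perf$fn))
  expect_true(perf$auc_ci[1] <= perf$auc && perf$auc <= perf$auc_ci[2])
  expect_true(all(perf$sensitivity_ci >= 0 & perf$sensitivity_ci <= 1))
  expect_output(print(perf), "AUC")
})
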