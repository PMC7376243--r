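# Diagnostic-test evaluation of cross-validated probabilities: ROC curve,
# AUC with DeLong (or bootstrap) 95% CI, operating-threshold selection,
# confusion statistics with exact binomial CIs, and a between-group
# Mann-Whitney p-value.

check_probs_labels <- function(probabilities, labels) {
  labels <- check_binary_labels(labels)
  if (length(probabilities) != length(labels)) {
    stop_argument("probabilities and labels must have equal length")
  }
  if (length(labels) == 0L) stop_argument("empty input")
  if (anyNA(probabilities) || any(!is.finite(probabilities))) {
    stop_argument("probabilities must be finite")
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    stop_degenerate("both classes must be present")
  }
  labels
}

#' ROC curve points
#'
#' One point per distinct probability threshold (prediction positive iff
#' probability >= threshold), prefixed with (0, 0); the final point is
#' always (1, 1).
#'
#' @param probabilities Predicted positive-class probabilities.
#' @param labels Binary outcome labels.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_curve <- function(probabilities, labels) {
  labels <- check_probs_labels(probabilities, labels)
  th <- sort(unique(probabilities), decreasing = TRUE)
  pos <- probabilities[labels == 1]; neg <- probabilities[labels == 0]
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve with 95% confidence interval
#'
#' The point estimate is the Mann-Whitney concordance probability:
#' (concordant positive-negative pairs + half the tied pairs) divided by
#' the number of pairs. The default CI is DeLong's asymptotic interval
#' from placement-value variances; a stratified bootstrap (resampling
#' positives and negatives separately) is available for cross-checking.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcome labels.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap draw.
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci_lower`, `ci_upper`, `ci_method`.
#' @export
auc <- function(probabilities, labels, ci_method = c("delong", "bootstrap"),
                n_boot = 2000L, seed = 1L, conf = 0.95) {
  labels <- check_probs_labels(probabilities, labels)
  ci_method <- match.arg(ci_method)
  x <- probabilities[labels == 1]; y <- probabilities[labels == 0]
  a <- auc_point(x, y)
  if (ci_method == "delong") {
    # Placement values: V10 for each positive, V01 for each negative.
    v10 <- vapply(x, function(xi) mean(y < xi) + 0.5 * mean(y == xi), numeric(1))
    v01 <- vapply(y, function(yj) mean(x > yj) + 0.5 * mean(x == yj), numeric(1))
    s2 <- safe_var(v10) / length(x) + safe_var(v01) / length(y)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- c(a - z * sqrt(s2), a + z * sqrt(s2))
  } else {
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      auc_point(sample(x, replace = TRUE), sample(y, replace = TRUE))
    }, numeric(1)))
    ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, type = 7)
  }
  list(auc = a, ci_lower = max(0, min(ci[1], a)),
       ci_upper = min(1, max(ci[2], a)), ci_method = ci_method)
}

auc_point <- function(x, y) {
  rk <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

safe_var <- function(v) if (length(v) > 1L) stats::var(v) else 0

#' Choose an operating threshold
#'
#' Default policy maximises Youden's J = sensitivity + specificity - 1 over
#' the observed probability cut-points; ties are broken toward the higher
#' threshold (higher specificity). The fixed-threshold policy returns
#' `fixed` unchanged, for reporting at a conventional 0.5 cut.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcome labels.
#' @param policy `"youden"` (default) or `"fixed"`.
#' @param fixed Threshold returned under the fixed policy.
#' @return A single threshold; predictions are positive at or above it.
#' @export
choose_threshold <- function(probabilities, labels,
                             policy = c("youden", "fixed"), fixed = 0.5) {
  policy <- match.arg(policy)
  labels <- check_probs_labels(probabilities, labels)
  if (policy == "fixed") return(fixed)
  pos <- probabilities[labels == 1]; neg <- probabilities[labels == 0]
  th <- sort(unique(probabilities), decreasing = TRUE)  # high spec first
  j <- vapply(th, function(t) mean(pos >= t) - mean(neg >= t), numeric(1))
  th[which.max(j)]
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (!is_count(n, 1L) || !is_count(x, 0L) || x > n) {
    stop_argument("need integer 0 <= x <= n, n >= 1")
  }
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower, upper)
}

#' Confusion statistics at a threshold
#'
#' Predictions are positive iff probability >= threshold. Sensitivity and
#' specificity carry exact Clopper-Pearson 95% CIs; PPV and NPV are point
#' estimates (at the analysed prevalence). Undefined rates (zero
#' denominator) are returned as `NaN` with a warning rather than an error.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcome labels.
#' @param threshold Decision threshold.
#' @return List with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`
#'   (each with `_ci` bounds), `ppv`, `npv`, `threshold`.
#' @export
confusion_stats <- function(probabilities, labels, threshold) {
  labels <- check_probs_labels(probabilities, labels)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- rate(tp, tp + fn, "sensitivity")
  spec <- rate(tn, tn + fp, "specificity")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens,
       sensitivity_ci = if (tp + fn > 0) clopper_pearson(tp, tp + fn) else c(NaN, NaN),
       specificity = spec,
       specificity_ci = if (tn + fp > 0) clopper_pearson(tn, tn + fp) else c(NaN, NaN),
       ppv = rate(tp, tp + fp, "ppv"),
       npv = rate(tn, tn + fn, "npv"),
       threshold = threshold)
}

#' Between-group p-value on predicted probabilities
#'
#' Two-sided Mann-Whitney test comparing the predicted probabilities of
#' positive-label vs negative-label samples.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcome labels.
#' @return A p-value.
#' @export
group_pvalue <- function(probabilities, labels) {
  labels <- check_probs_labels(probabilities, labels)
  mw_test(probabilities[labels == 1], probabilities[labels == 0])$p
}

#' Assemble a full diagnostic performance report
#'
#' Combines AUC + CI, the chosen operating threshold, confusion statistics
#' with CIs, and the between-group p-value into one record.
#'
#' @param probabilities Out-of-fold predicted probabilities.
#' @param labels Binary outcome labels.
#' @param threshold_policy Passed to [choose_threshold()].
#' @param fixed_threshold Threshold under the `"fixed"` policy.
#' @param ci_method AUC CI method, see [auc()].
#' @param seed Seed for the bootstrap CI, if selected.
#' @return An object of class `voc_performance` (a list).
#' @export
performance_report <- function(probabilities, labels,
                               threshold_policy = c("youden", "fixed"),
                               fixed_threshold = 0.5,
                               ci_method = c("delong", "bootstrap"),
                               seed = 1L) {
  threshold_policy <- match.arg(threshold_policy)
  ci_method <- match.arg(ci_method)
  labels <- check_probs_labels(probabilities, labels)
  a <- auc(probabilities, labels, ci_method = ci_method, seed = seed)
  th <- choose_threshold(probabilities, labels, policy = threshold_policy,
                         fixed = fixed_threshold)
  cs <- confusion_stats(probabilities, labels, th)
  structure(c(list(auc = a$auc, auc_ci = c(a$ci_lower, a$ci_upper),
                   auc_ci_method = a$ci_method,
                   threshold_policy = threshold_policy),
              cs,
              list(group_p = group_pvalue(probabilities, labels),
                   n_positive = sum(labels == 1),
                   n_negative = sum(labels == 0))),
            class = "voc_performance")
}

#' @export
print.voc_performance <- function(x, ...) {
  fmt_ci <- function(v, ci) sprintf("%.2f (%.2f-%.2f)", v, ci[1], ci[2])
  cat(sprintf(
    paste0("<voc_performance> n = %d pos / %d neg\n",
           "  AUC         %s\n  Sensitivity %s\n  Specificity %s\n",
           "  PPV %.2f  NPV %.2f  threshold %.3f (%s)\n",
           "  between-group p %s\n"),
    x$n_positive, x$n_negative,
    fmt_ci(x$auc, x$auc_ci),
    fmt_ci(x$sensitivity, x$sensitivity_ci),
    fmt_ci(x$specificity, x$specificity_ci),
    x$ppv, x$npv, x$threshold, x$threshold_policy,
    format.pval(x$group_p, digits = 3, eps = 0.001)))
  invisible(x)
}
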