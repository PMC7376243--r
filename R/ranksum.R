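# Two-sample Mann-Whitney rank-sum machinery. Used three ways: per-feature
# ranking during cross-validated feature selection, the between-group
# p-value on out-of-fold probabilities, and the nonparametric branch of
# cohort group comparisons.
#
# Small samples (both groups <= 8) get an exact conditional test by
# enumerating all assignments of the observed (tie-averaged) ranks to the
# two groups; larger samples use the normal approximation with tie
# correction and continuity correction, matching stats::wilcox.test's
# approximate path.

#' Two-sided Mann-Whitney rank-sum test
#'
#' @param x,y Numeric samples for the two groups.
#' @return List with `p` (two-sided p-value), `u` (U statistic of `x`),
#'   `auc` (U scaled to the concordance probability P(X > Y) + 0.5 P(X = Y)),
#'   and `method` ("exact" or "normal").
#' @export
mw_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_degenerate("both groups must be non-empty")
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  if (max(n1, n2) <= 8L) {
    uu <- mw_exact_null(rk, n1)
    p <- min(1, 2 * min(mean(uu <= u + 1e-9), mean(uu >= u - 1e-9)))
    list(p = p, u = u, auc = auc, method = "exact")
  } else {
    n <- n1 + n2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(list(p = 1, u = u, auc = auc, method = "normal"))
    z <- max(abs(u - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2)
    list(p = min(1, 2 * stats::pnorm(-z)), u = u, auc = auc, method = "normal")
  }
}

# Null distribution of U over all C(n, n1) assignments of the observed
# ranks to group 1 (conditional on ties).
mw_exact_null <- function(rk, n1) {
  combs <- utils::combn(length(rk), n1)
  colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
}

# Average column ranks and tie corrections for an n x p matrix, fully
# vectorised (no per-column apply); the selection step calls this on
# matrices with tens of thousands of columns.
col_ranks <- function(X) {
  n <- nrow(X); p <- ncol(X); N <- n * p
  cid <- rep.int(seq_len(p), rep.int(n, p))
  o <- order(cid, as.vector(X))          # stable: columns stay contiguous
  v <- as.vector(X)[o]
  newg <- c(TRUE, v[-1] != v[-N] | cid[-1] != cid[-N])
  g <- cumsum(newg)
  pos <- rep.int(seq_len(n), p)          # within-column position after sort
  first <- which(newg)
  last <- c(first[-1] - 1L, N)
  gmean <- (pos[first] + pos[last]) / 2
  r <- gmean[g]
  R <- matrix(0, n, p)
  R[o] <- r
  gsize <- last - first + 1L
  tie <- numeric(p)
  agg <- rowsum(as.numeric(gsize)^3 - gsize, cid[first])
  tie[as.integer(rownames(agg))] <- agg[, 1]
  list(ranks = R, tie_term = tie)
}

# Per-feature two-sided Mann-Whitney p-values and rank-biserial effects for
# a samples x features matrix. Constant features get p = 1, effect = 0.
ranksum_feature_stats <- function(X, labels) {
  labels <- check_binary_labels(labels)
  n1 <- sum(labels == 1); n2 <- sum(labels == 0)
  if (n1 == 0L || n2 == 0L) stop_degenerate("both classes must be present")
  p_feat <- ncol(X)
  const <- matrixStats_colconst(X)
  if (max(n1, n2) <= 8L) {
    # Exact conditional test, vectorised across features: the null W
    # distribution for every feature is one indicator-matrix product over
    # the shared C(n, n1) subsets, chunked to bound memory. Constant
    # features (common in sparse thresholded spectra) are skipped.
    pv <- rep(1, p_feat)
    eff <- rep(0, p_feat)
    active <- which(!const)
    if (length(active)) {
      cr <- col_ranks(X[, active, drop = FALSE])
      combs <- utils::combn(n1 + n2, n1)
      m <- ncol(combs)
      Ind <- matrix(0, m, n1 + n2)
      Ind[cbind(rep(seq_len(m), each = n1), as.vector(combs))] <- 1
      w_obs <- colSums(cr$ranks[labels == 1, , drop = FALSE])
      chunk <- max(1L, floor(4e6 / m))
      for (start in seq.int(1L, length(active), by = chunk)) {
        j <- seq.int(start, min(start + chunk - 1L, length(active)))
        Wnull <- Ind %*% cr$ranks[, j, drop = FALSE]
        ref <- rep(w_obs[j], each = m)
        le <- colMeans(Wnull <= ref + 1e-9)
        ge <- colMeans(Wnull >= ref - 1e-9)
        pv[active[j]] <- pmin(1, 2 * pmin(le, ge))
      }
      eff[active] <- 2 * ((w_obs - n1 * (n1 + 1) / 2) / (n1 * n2)) - 1
    }
  } else {
    cr <- col_ranks(X)
    W1 <- colSums(cr$ranks[labels == 1, , drop = FALSE])
    U1 <- W1 - n1 * (n1 + 1) / 2
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - cr$tie_term / (n * (n - 1)))
    z <- pmax(abs(U1 - n1 * n2 / 2) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
    pv <- pmin(1, 2 * stats::pnorm(-z))
    pv[sigma2 <= 0] <- 1
    eff <- 2 * (U1 / (n1 * n2)) - 1
    eff[sigma2 <= 0] <- 0
  }
  pv[const] <- 1
  eff[const] <- 0
  list(p = pv, effect = eff)
}

# TRUE for columns constant across all rows.
matrixStats_colconst <- function(X) {
  if (nrow(X) <= 1L) return(rep(TRUE, ncol(X)))
  colSums(X != rep(X[1L, ], each = nrow(X))) == 0L
}
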