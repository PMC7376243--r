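# Independent brute-force oracles. These deliberately use different
# computational routes from the package (pair counting instead of ranks,
# tail summation instead of beta quantiles, exhaustive window search
# instead of greedy trimming) so agreement is informative.

# Two-sided exact Mann-Whitney p by enumerating every assignment of the
# pooled observations to group 1, with U computed by direct pair counting.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  uu <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(uu <= u_obs + 1e-9), mean(uu >= u_obs - 1e-9)))
}

# AUC by explicit concordant / tied pair counting.
oracle_auc <- function(prob, labels) {
  pos <- prob[labels == 1]; neg <- prob[labels == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Clopper-Pearson bounds by inverting the binomial tail sums directly.
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else {
    stats::uniroot(function(p) sum(stats::dbinom(x:n, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    stats::uniroot(function(p) sum(stats::dbinom(0:x, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower, upper)
}

# Exhaustive search for the smallest-area window holding >= coverage of
# total above-threshold mass (feasible only on small grids).
oracle_crop_window <- function(spectra, threshold, coverage = 1) {
  M <- Reduce(`+`, lapply(spectra, function(sp) {
    m <- sp$intensities; m[m < threshold] <- 0; m
  }))
  total <- sum(M)
  best <- NULL; best_area <- Inf
  for (rlo in 0:(nrow(M) - 1)) for (rhi in (rlo + 1):nrow(M))
    for (dlo in 0:(ncol(M) - 1)) for (dhi in (dlo + 1):ncol(M)) {
      mass <- sum(M[(rlo + 1):rhi, (dlo + 1):dhi])
      area <- (rhi - rlo) * (dhi - dlo)
      if (mass >= coverage * total && area < best_area) {
        best_area <- area
        best <- c(rlo, rhi, dlo, dhi)
      }
    }
  best
}

# Trapezoidal area under an ROC curve data frame.
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# Quick builder for a spectrum around a plain matrix (unit axes).
make_spec <- function(m, id = "t") {
  ims_spectrum(id, seq_len(nrow(m)), seq_len(ncol(m)), m)
}

# Tiny spectrum parameters for fast cohort-level tests.
tiny_sim <- function(...) {
  spectrum_sim_params(n_retention = 40L, n_drift = 30L, n_peaks = 8L, ...)
}
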