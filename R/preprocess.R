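# Dimensionality reduction for GC-IMS spectra: a rectangular crop shared by
# all samples, a background threshold, and flattening to a samples x
# features matrix. Raw runs are dense and huge (order 10^7 cells) but most
# cells are background; crop + threshold cut the non-zero cell count by one
# to two orders of magnitude before any modelling.
#
# Coordinate convention: all windows are 0-based and half-open
# ([lo, hi) on both axes), so composing and comparing windows never has
# off-by-one ambiguity.

#' Rectangular crop window over a spectrum grid
#'
#' Indices are 0-based and half-open: row `retention_lo` is included,
#' `retention_hi` excluded, and likewise for the drift axis.
#'
#' @param retention_lo,retention_hi Row index range into the retention axis.
#' @param drift_lo,drift_hi Column index range into the drift axis.
#' @return An object of class `crop_window`.
#' @export
crop_window <- function(retention_lo, retention_hi, drift_lo, drift_hi) {
  w <- structure(
    list(retention_lo = as.integer(retention_lo),
         retention_hi = as.integer(retention_hi),
         drift_lo = as.integer(drift_lo),
         drift_hi = as.integer(drift_hi)),
    class = "crop_window")
  with(w, {
    if (retention_lo < 0L || drift_lo < 0L ||
        retention_lo >= retention_hi || drift_lo >= drift_hi) {
      stop_argument("crop window must satisfy 0 <= lo < hi on both axes")
    }
  })
  w
}

#' @export
print.crop_window <- function(x, ...) {
  cat(sprintf("<crop_window> retention [%d,%d) x drift [%d,%d)\n",
              x$retention_lo, x$retention_hi, x$drift_lo, x$drift_hi))
  invisible(x)
}

check_window_fits <- function(window, n_retention, n_drift) {
  if (window$retention_hi > n_retention || window$drift_hi > n_drift) {
    stop_bounds(sprintf(
      "crop window [%d,%d)x[%d,%d) exceeds spectrum dimensions %d x %d",
      window$retention_lo, window$retention_hi,
      window$drift_lo, window$drift_hi, n_retention, n_drift))
  }
  invisible(window)
}

#' Preprocessing configuration: crop plus background threshold
#'
#' @param crop A [crop_window()], applied identically to every sample.
#' @param threshold Non-negative intensity cutoff; cells strictly below it
#'   are zeroed (cells equal to the threshold survive).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop, threshold) {
  if (!inherits(crop, "crop_window")) stop_argument("crop must be a crop_window")
  if (!is_number(threshold) || threshold < 0) {
    stop_argument("threshold must be a non-negative number")
  }
  structure(list(crop = crop, threshold = as.numeric(threshold)),
            class = "preprocess_config")
}

#' Crop a spectrum to a window
#'
#' @param sp An [ims_spectrum()].
#' @param window A [crop_window()] valid for the spectrum's dimensions.
#' @return A new `ims_spectrum` whose axes are the window's sub-ranges.
#' @export
crop_spectrum <- function(sp, window) {
  validate_spectrum(sp)
  check_window_fits(window, length(sp$retention), length(sp$drift))
  ri <- seq.int(window$retention_lo + 1L, window$retention_hi)
  di <- seq.int(window$drift_lo + 1L, window$drift_hi)
  ims_spectrum(sp$sample_id, sp$retention[ri], sp$drift[di],
               sp$intensities[ri, di, drop = FALSE])
}

#' Zero background cells below a threshold
#'
#' Every cell with intensity strictly below `threshold` is set to 0; cells
#' at or above it are unchanged. Dimensions are unchanged.
#'
#' @param sp An [ims_spectrum()].
#' @param threshold Non-negative cutoff.
#' @return A new `ims_spectrum`.
#' @export
apply_threshold <- function(sp, threshold) {
  validate_spectrum(sp)
  if (!is_number(threshold) || threshold < 0) {
    stop_argument("threshold must be a non-negative number")
  }
  m <- sp$intensities
  m[m < threshold] <- 0
  ims_spectrum(sp$sample_id, sp$retention, sp$drift, m)
}

check_shared_axes <- function(spectra) {
  if (length(spectra) < 1L) stop_argument("need at least one spectrum")
  lapply(spectra, validate_spectrum)
  r0 <- spectra[[1]]$retention; d0 <- spectra[[1]]$drift
  for (sp in spectra[-1]) {
    if (!identical(sp$retention, r0) || !identical(sp$drift, d0)) {
      stop_argument("all spectra must share identical retention and drift axes")
    }
  }
  invisible(spectra)
}

#' Suggest a crop window covering the informative region
#'
#' An automated stand-in for the manual one-time crop selection done by
#' inspecting many samples: starting from the full grid, edge rows/columns
#' are greedily trimmed (always the edge carrying the least above-threshold
#' mass) while the window still holds at least `coverage` of the total
#' above-threshold intensity summed over all spectra. The returned window
#' is then frozen in a [preprocess_config()] and applied to every sample,
#' train and test alike.
#'
#' @param spectra List of `ims_spectrum` with identical axes.
#' @param threshold Background cutoff defining "informative" intensity.
#' @param coverage Fraction in (0, 1] of total above-threshold intensity
#'   the window must retain.
#' @return A [crop_window()].
#' @export
suggest_crop_window <- function(spectra, threshold, coverage = 1) {
  check_shared_axes(spectra)
  if (!is_number(coverage) || coverage <= 0 || coverage > 1) {
    stop_argument("coverage must be in (0, 1]")
  }
  M <- Reduce(`+`, lapply(spectra, function(sp) {
    m <- sp$intensities
    m[m < threshold] <- 0
    m
  }))
  total <- sum(M)
  if (total <= 0) stop_degenerate("no cell at or above the threshold in any spectrum")
  need <- coverage * total

  rlo <- 0L; rhi <- nrow(M); dlo <- 0L; dhi <- ncol(M)
  mass <- total
  repeat {
    cand_mass <- c(
      top    = if (rhi - rlo > 1L) sum(M[rlo + 1L, (dlo + 1L):dhi]) else Inf,
      bottom = if (rhi - rlo > 1L) sum(M[rhi,      (dlo + 1L):dhi]) else Inf,
      left   = if (dhi - dlo > 1L) sum(M[(rlo + 1L):rhi, dlo + 1L]) else Inf,
      right  = if (dhi - dlo > 1L) sum(M[(rlo + 1L):rhi, dhi])      else Inf)
    ok <- which(is.finite(cand_mass) & (mass - cand_mass) >= need)
    if (length(ok) == 0L) break
    pick <- ok[which.min(cand_mass[ok])]
    mass <- mass - cand_mass[pick]
    switch(names(cand_mass)[pick],
           top = rlo <- rlo + 1L, bottom = rhi <- rhi - 1L,
           left = dlo <- dlo + 1L, right = dhi <- dhi - 1L)
  }
  crop_window(rlo, rhi, dlo, dhi)
}

#' Build the samples x features matrix
#'
#' Each sample's cropped, thresholded intensity matrix is flattened in
#' row-major order (retention index varying slowest), so every sample maps
#' onto the identical feature grid. Samples whose in-crop cells all fall
#' below the threshold produce an all-zero row and are retained. The
#' achieved non-zero reduction factor (non-zero cells in the raw spectra
#' divided by non-zero cells after crop + threshold) is stored in the
#' result and reported with `message()` when `verbose = TRUE`.
#'
#' @param spectra List of `ims_spectrum` with identical axes.
#' @param labels Binary (0/1) vector, one label per spectrum.
#' @param config A [preprocess_config()].
#' @param verbose Emit a message with the reduction factor.
#' @return An object of class `voc_features`: list with `sample_ids`,
#'   `feature_index` (data frame of 0-based `retention_idx`, `drift_idx`),
#'   `values` (samples x features matrix), `labels`, `config` and
#'   `reduction_factor`.
#' @export
build_feature_matrix <- function(spectra, labels, config, verbose = FALSE) {
  check_shared_axes(spectra)
  if (length(labels) != length(spectra)) {
    stop_argument("labels must align one-to-one with spectra")
  }
  labels <- check_binary_labels(labels)
  if (!inherits(config, "preprocess_config")) {
    stop_argument("config must be a preprocess_config")
  }
  w <- config$crop
  check_window_fits(w, length(spectra[[1]]$retention), length(spectra[[1]]$drift))

  nz_before <- 0; nz_after <- 0
  rows <- lapply(spectra, function(sp) {
    nz_before <<- nz_before + sum(sp$intensities != 0)
    m <- apply_threshold(crop_spectrum(sp, w), config$threshold)$intensities
    nz_after <<- nz_after + sum(m != 0)
    as.vector(t(m))  # row-major: drift index varies fastest
  })
  values <- do.call(rbind, rows)
  nr <- w$retention_hi - w$retention_lo
  nd <- w$drift_hi - w$drift_lo
  feature_index <- data.frame(
    retention_idx = rep(seq.int(w$retention_lo, w$retention_hi - 1L), each = nd),
    drift_idx = rep.int(seq.int(w$drift_lo, w$drift_hi - 1L), nr))
  reduction <- if (nz_after > 0) nz_before / nz_after else Inf
  if (verbose) {
    message(sprintf(
      "feature matrix: %d samples x %d features; non-zero reduction factor %.1f",
      length(spectra), nrow(feature_index), reduction))
  }
  sample_ids <- vapply(spectra, `[[`, character(1), "sample_id")
  rownames(values) <- sample_ids
  structure(
    list(sample_ids = sample_ids,
         feature_index = feature_index,
         values = values,
         labels = labels,
         config = config,
         reduction_factor = reduction),
    class = "voc_features")
}

#' @export
print.voc_features <- function(x, ...) {
  cat(sprintf(
    "<voc_features> %d samples x %d features (%d positive / %d negative); reduction factor %.1f\n",
    length(x$sample_ids), ncol(x$values), sum(x$labels == 1), sum(x$labels == 0),
    x$reduction_factor))
  invisible(x)
}

# Row subset of a feature matrix, preserving order.
fm_subset <- function(fm, idx) {
  structure(
    list(sample_ids = fm$sample_ids[idx],
         feature_index = fm$feature_index,
         values = fm$values[idx, , drop = FALSE],
         labels = fm$labels[idx],
         config = fm$config,
         reduction_factor = fm$reduction_factor),
    class = "voc_features")
}
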