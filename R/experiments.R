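# Simulation experiments used to validate the pipeline: balanced labelled
# sample sets, single-call pipeline AUC (preprocess -> CV -> AUC), and the
# feature-selection leakage demonstration.

#' Simulate a balanced, labelled set of spectra
#'
#' Generates `n` spectra with labels split half negative / half positive;
#' positives carry the multiplicative amplitude effect on `effect_peaks`.
#'
#' @param n Number of samples (even).
#' @param params A [spectrum_sim_params()].
#' @param effect_size Amplitude multiplier for positives (1 = null).
#' @param effect_peaks Indices of affected peaks.
#' @param seed Seed; each sample gets an independent sub-seed.
#' @return List with `spectra` (list) and `labels` (0/1 vector).
#' @export
simulate_sample_set <- function(n = 100L, params = spectrum_sim_params(),
                                effect_size = 1,
                                effect_peaks = seq_len(min(10L, params$n_peaks)),
                                seed = 1L) {
  if (!is_count(n, 2L) || n %% 2L != 0L) stop_argument("n must be a positive even integer")
  labels <- rep(c(0L, 1L), each = n %/% 2L)
  seeds <- derive_seeds(seed, n)
  spectra <- lapply(seq_len(n), function(i) {
    generate_spectrum(params, class_label = labels[i],
                      effect_peaks = effect_peaks, effect_size = effect_size,
                      seed = seeds[i], sample_id = sprintf("sim%03d", i))
  })
  list(spectra = spectra, labels = labels)
}

# Default background threshold for simulated spectra: five baseline-noise
# standard deviations (with sd 1 that passes ~3e-7 of pure-noise cells).
default_sim_threshold <- function(params) max(5 * params$baseline_noise_sd, 1e-8)

#' Run the full pipeline on one simulated sample set and return its AUC
#'
#' Generates a balanced labelled sample set, freezes a crop window from the
#' data (as the one-time manual crop selection would), builds the feature
#' matrix, runs stratified cross-validation with in-fold rank-sum feature
#' selection, and evaluates the out-of-fold AUC.
#'
#' @param n Number of samples.
#' @param effect_size Amplitude multiplier for the positive class.
#' @param classifier `"random_forest"` or `"gaussian_process"`.
#' @param seed Seed driving simulation, folds and training.
#' @param params A [spectrum_sim_params()].
#' @param threshold Background threshold (default: 5 noise sd).
#' @param coverage Crop coverage target, see [suggest_crop_window()].
#' @param n_folds,n_features CV settings, see [model_config()].
#' @param leaky Use the broken whole-dataset feature selection
#'   ([run_cv_leaky()]) instead of in-fold selection — negative control.
#' @return List with `auc`, `n_samples`, `n_features`,
#'   `reduction_factor`, and the `cv` result.
#' @export
pipeline_auc <- function(n = 100L, effect_size = 1,
                         classifier = "random_forest", seed = 1L,
                         params = spectrum_sim_params(),
                         threshold = default_sim_threshold(params),
                         coverage = 0.99,
                         n_folds = 10L, n_features = 100L,
                         leaky = FALSE) {
  seeds <- derive_seeds(seed, 2L)
  ss <- simulate_sample_set(n, params, effect_size, seed = seeds[1])
  crop <- suggest_crop_window(ss$spectra, threshold, coverage)
  fm <- build_feature_matrix(ss$spectra, ss$labels,
                             preprocess_config(crop, threshold))
  cfg <- model_config(classifier, n_folds = n_folds, n_features = n_features,
                      seed = seeds[2])
  cv <- if (leaky) run_cv_leaky(fm, cfg) else run_cv(fm, cfg)
  a <- auc(cv$probabilities, cv$labels)
  list(auc = a$auc, n_samples = n, n_features = ncol(fm$values),
       reduction_factor = fm$reduction_factor, cv = cv)
}

#' Demonstrate feature-selection leakage on null data
#'
#' On label-free (null) data with many features and few samples, selecting
#' features on the full dataset before cross-validation inflates apparent
#' AUC far above chance, while in-fold selection stays near 0.5. Runs both
#' variants on the *same* simulated null data.
#'
#' @param seed Seed.
#' @param n Number of samples (<= 60 makes the inflation pronounced).
#' @param n_retention,n_drift Grid for the noise-only spectra; the product
#'   is the feature count (default 50 x 40 = 2000 features).
#' @param classifier Classifier used for both variants.
#' @return Named vector `c(infold = ..., leaky = ...)` of AUCs.
#' @export
leakage_experiment <- function(seed = 1L, n = 60L,
                               n_retention = 50L, n_drift = 40L,
                               classifier = "random_forest") {
  params <- spectrum_sim_params(n_retention = n_retention, n_drift = n_drift,
                                n_peaks = 0L, rip_intensity = 0,
                                baseline_noise_sd = 1)
  seeds <- derive_seeds(seed, 2L)
  ss <- simulate_sample_set(n, params, effect_size = 1, effect_peaks = integer(0),
                            seed = seeds[1])
  crop <- crop_window(0L, n_retention, 0L, n_drift)
  fm <- build_feature_matrix(ss$spectra, ss$labels,
                             preprocess_config(crop, 0))
  cfg <- model_config(classifier, seed = seeds[2])
  correct <- run_cv(fm, cfg)
  leaky <- run_cv_leaky(fm, cfg)
  c(infold = auc(correct$probabilities, correct$labels)$auc,
    leaky = auc(leaky$probabilities, leaky$labels)$auc)
}
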