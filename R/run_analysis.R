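# End-to-end orchestration: cohort + spectra -> three analyses (BV, preterm
# from the first swab, preterm from the swab closest to delivery), each
# cross-validated with both classifiers, reported in one structured record
# that serialises to JSON byte-identically for a fixed seed and config.

#' Assemble a run configuration
#'
#' @param patients,swabs Cohort data frames (see cohort module).
#' @param spectra Named list of [ims_spectrum()] keyed by swab `sample_id`.
#' @param threshold Background threshold.
#' @param crop Optional [crop_window()]; when `NULL`, one window is frozen
#'   from all spectra via [suggest_crop_window()] and applied to every
#'   analysis, train and test alike.
#' @param coverage Coverage for the automatic crop.
#' @param classifiers Character vector of classifiers to fit.
#' @param analyses Named list of `list(endpoint=, swab_mode=)` blocks; the
#'   default is the three-analysis design: BV from the first swab, preterm
#'   from the first swab, preterm from the swab closest to delivery.
#' @param n_folds,n_features,ntree,gp_length_scale Model settings, see
#'   [model_config()].
#' @param threshold_policy Operating-point policy, see [choose_threshold()].
#' @param ci_method AUC CI method, see [auc()].
#' @param seed Master seed for balancing, folds and training.
#' @return An object of class `voc_run_config`.
#' @export
run_config <- function(patients, swabs, spectra,
                       threshold, crop = NULL, coverage = 0.99,
                       classifiers = c("random_forest", "gaussian_process"),
                       analyses = list(
                         bv = list(endpoint = "bv", swab_mode = "first"),
                         preterm_first = list(endpoint = "preterm",
                                              swab_mode = "first"),
                         preterm_closest = list(endpoint = "preterm",
                                                swab_mode = "closest_to_delivery")),
                       n_folds = 10L, n_features = 100L, ntree = 1000L,
                       gp_length_scale = NULL,
                       threshold_policy = "youden",
                       ci_method = "delong", seed = 1L) {
  if (is.null(names(spectra)) || any(!nzchar(names(spectra)))) {
    stop_config("spectra must be a named list keyed by sample_id")
  }
  missing <- setdiff(swabs$sample_id, names(spectra))
  if (length(missing)) {
    stop_config(sprintf("no spectrum for %d swab(s), e.g. '%s'",
                        length(missing), missing[1]))
  }
  structure(list(patients = patients, swabs = swabs, spectra = spectra,
                 threshold = threshold, crop = crop, coverage = coverage,
                 classifiers = classifiers, analyses = analyses,
                 n_folds = as.integer(n_folds),
                 n_features = as.integer(n_features),
                 ntree = as.integer(ntree), gp_length_scale = gp_length_scale,
                 threshold_policy = threshold_policy, ci_method = ci_method,
                 seed = as.integer(seed)),
            class = "voc_run_config")
}

performance_block <- function(perf) {
  list(auc = perf$auc, auc_ci = perf$auc_ci,
       sensitivity = perf$sensitivity, sensitivity_ci = perf$sensitivity_ci,
       specificity = perf$specificity, specificity_ci = perf$specificity_ci,
       ppv = perf$ppv, npv = perf$npv,
       group_p = perf$group_p, threshold = perf$threshold,
       confusion = list(tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn))
}

timing_block <- function(patients, swabs, set) {
  # median (IQR) swab-timing summaries by outcome group, in days
  sw <- swabs[match(set$sample_id, swabs$sample_id), , drop = FALSE]
  deliv <- patients$delivery_days[match(set$patient_id, patients$patient_id)]
  out <- list()
  for (grp in c(1, 0)) {
    sel <- set$label == grp
    nm <- if (grp == 1) "positive" else "negative"
    g <- sw$gestation_days[sel]
    out[[paste0("gestation_at_swab_", nm)]] <-
      as.list(median_iqr(g))
    if (any(!is.na(deliv[sel]))) {
      out[[paste0("weeks_to_delivery_", nm)]] <-
        as.list(median_iqr((deliv[sel] - g) / 7))
    }
  }
  if (all(!is.na(deliv))) {
    out$gestation_at_swab_p <- mw_test(sw$gestation_days[set$label == 1],
                                       sw$gestation_days[set$label == 0])$p
  }
  out
}

#' Run the full three-analysis study on a cohort
#'
#' Executes, for every analysis block in the config: analysis-set
#' construction (with the preterm exclusion rules), feature-matrix
#' construction under the frozen crop + threshold, class balancing by
#' random undersampling, stratified cross-validation with in-fold rank-sum
#' feature selection for each requested classifier, and diagnostic-test
#' evaluation. The report embeds the seed and a hash of the configuration
#' settings; identical config + seed reproduce the report byte-identically.
#'
#' @param config A [run_config()].
#' @param verbose Log progress and reduction factors with `message()`.
#' @return A nested report list (class `voc_report`).
#' @export
run_analysis <- function(config, verbose = FALSE) {
  if (!inherits(config, "voc_run_config")) stop_argument("config must be a run_config")
  spectra <- config$spectra
  crop <- config$crop
  if (is.null(crop)) {
    crop <- suggest_crop_window(unname(spectra), config$threshold,
                                config$coverage)
  }
  pconf <- preprocess_config(crop, config$threshold)
  settings <- config[setdiff(names(config), c("patients", "swabs", "spectra"))]
  seeds <- derive_seeds(config$seed, length(config$analyses))
  report <- list(
    seed = config$seed,
    config_hash = rlang::hash(settings),
    preprocess = list(crop = unclass(crop), threshold = config$threshold),
    analyses = list())

  for (ai in seq_along(config$analyses)) {
    aname <- names(config$analyses)[ai]
    spec <- config$analyses[[ai]]
    block <- withCallingHandlers(
      run_one_analysis(config, spec, pconf, seeds[ai], verbose),
      error = function(e) {
        stop(errorCondition(
          sprintf("analysis '%s' (%s, %s): %s", aname, spec$endpoint,
                  spec$swab_mode, conditionMessage(e)),
          class = class(e)))
      })
    report$analyses[[aname]] <- block
  }
  structure(report, class = c("voc_report", "list"))
}

run_one_analysis <- function(config, spec, pconf, seed, verbose) {
  set <- build_analysis_set(config$patients, config$swabs,
                            endpoint = spec$endpoint,
                            swab_mode = spec$swab_mode)
  fm <- build_feature_matrix(config$spectra[set$sample_id], set$label, pconf,
                             verbose = verbose)
  seeds <- derive_seeds(seed, 1L + length(config$classifiers))
  bal <- balance_classes(fm, seeds[1])
  block <- list(endpoint = spec$endpoint, swab_mode = spec$swab_mode,
                n_patients = nrow(set),
                n_balanced = length(bal$labels),
                reduction_factor = fm$reduction_factor,
                timing = timing_block(config$patients, config$swabs, set),
                classifiers = list())
  for (ci in seq_along(config$classifiers)) {
    cl <- config$classifiers[ci]
    cfg <- model_config(cl, n_folds = config$n_folds,
                        n_features = config$n_features,
                        ntree = config$ntree,
                        gp_length_scale = config$gp_length_scale,
                        seed = seeds[1L + ci])
    cv <- run_cv(bal, cfg)
    if (verbose) {
      message(sprintf("  %s/%s: %d balanced samples, %d features/fold",
                      spec$endpoint, cl, length(bal$labels),
                      length(cv$selected_features[[1]])))
    }
    perf <- performance_report(cv$probabilities, cv$labels,
                               threshold_policy = config$threshold_policy,
                               ci_method = config$ci_method,
                               seed = seeds[1L + ci])
    block$classifiers[[cl]] <- performance_block(perf)
  }
  block
}

#' Serialise a report to JSON
#'
#' Deterministic output: fixed field order, 10 significant digits, no
#' timestamps, so identical runs produce byte-identical files.
#'
#' @param report A `voc_report` from [run_analysis()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Flatten a report into a classifier-by-analysis table
#'
#' @param report A `voc_report`.
#' @return Data frame with one row per (analysis, classifier) block.
#' @export
report_table <- function(report) {
  rows <- list()
  for (aname in names(report$analyses)) {
    a <- report$analyses[[aname]]
    for (cl in names(a$classifiers)) {
      b <- a$classifiers[[cl]]
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = aname, endpoint = a$endpoint, swab_mode = a$swab_mode,
        classifier = cl, n_balanced = a$n_balanced,
        auc = b$auc, auc_lo = b$auc_ci[1], auc_hi = b$auc_ci[2],
        sensitivity = b$sensitivity,
        sens_lo = b$sensitivity_ci[1], sens_hi = b$sensitivity_ci[2],
        specificity = b$specificity,
        spec_lo = b$specificity_ci[1], spec_hi = b$specificity_ci[2],
        ppv = b$ppv, npv = b$npv, group_p = b$group_p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
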