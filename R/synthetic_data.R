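# Synthetic GC-IMS spectra and obstetric cohorts. The generator targets
# the *statistical* structure the analysis pipeline assumes — a dense 2D
# grid with Gaussian baseline noise, a constant reactant-ion (RIP) column,
# 2D-Gaussian analyte peaks with a shared layout across samples, and a
# multiplicative class effect on a subset of peak amplitudes — not VOC
# chemistry. Cohorts are drawn with configurable preterm prevalence, BV
# prevalence and BV-to-preterm enrichment.

#' Simulation parameters for a GC-IMS spectrum
#'
#' The default 300 x 200 grid is a desk-scale stand-in for the millions of
#' cells of a real run. The peak *layout* (positions, base amplitudes,
#' widths) is drawn once from `layout_seed` and then shared by every sample
#' generated with these parameters, mimicking a fixed analyte panel;
#' per-sample variation comes from amplitude jitter and baseline noise in
#' [generate_spectrum()].
#'
#' @param n_retention,n_drift Grid dimensions (rows x columns), each >= 8.
#' @param retention_step Retention-axis spacing in seconds.
#' @param drift_start,drift_step Drift-axis origin and spacing in ms.
#' @param rip_drift_index 1-based column of the reactant-ion line.
#' @param rip_intensity Intensity of the RIP column (constant; analyte
#'   depletion of the RIP is not modelled).
#' @param n_peaks Number of analyte peaks.
#' @param peak_retention,peak_drift,peak_amplitude,sigma_retention,sigma_drift
#'   Optional explicit peak layout (axis units); all length `n_peaks`.
#'   When `NULL`, drawn from `layout_seed`.
#' @param amp_jitter_sd Log-normal sd of per-sample amplitude jitter.
#' @param baseline_noise_sd Gaussian baseline noise sd.
#' @param layout_seed Seed for the one-time peak layout draw.
#' @return An object of class `spectrum_sim_params`.
#' @export
spectrum_sim_params <- function(n_retention = 300L, n_drift = 200L,
                                retention_step = 1, drift_start = 5,
                                drift_step = 0.05,
                                rip_drift_index = 30L, rip_intensity = 50,
                                n_peaks = 30L,
                                peak_retention = NULL, peak_drift = NULL,
                                peak_amplitude = NULL,
                                sigma_retention = NULL, sigma_drift = NULL,
                                amp_jitter_sd = 0.15,
                                baseline_noise_sd = 1,
                                layout_seed = 1209L) {
  if (!is_count(n_retention, 8L) || !is_count(n_drift, 8L)) {
    stop_argument("grid dimensions must be integers >= 8")
  }
  if (!is_count(n_peaks, 0L)) stop_argument("n_peaks must be a non-negative integer")
  if (!is_number(baseline_noise_sd) || baseline_noise_sd < 0) {
    stop_argument("baseline_noise_sd must be >= 0")
  }
  if (!is_count(rip_drift_index, 1L) || rip_drift_index > n_drift) {
    stop_argument("rip_drift_index out of range")
  }
  retention <- (seq_len(n_retention) - 1) * retention_step
  drift <- drift_start + (seq_len(n_drift) - 1) * drift_step
  if (n_peaks > 0L && is.null(peak_retention)) {
    layout <- with_seed(layout_seed, list(
      r = stats::runif(n_peaks, 0.15, 0.85) * max(retention),
      d = drift_start + stats::runif(n_peaks, 0.30, 0.95) *
        (max(drift) - drift_start),
      a = stats::rlnorm(n_peaks, log(30), 0.4),
      sr = stats::runif(n_peaks, 2, 4) * retention_step,
      sd = stats::runif(n_peaks, 1.5, 3) * drift_step))
    peak_retention <- layout$r; peak_drift <- layout$d
    peak_amplitude <- layout$a
    sigma_retention <- layout$sr; sigma_drift <- layout$sd
  }
  if (n_peaks > 0L) {
    lens <- lengths(list(peak_retention, peak_drift, peak_amplitude,
                         sigma_retention, sigma_drift))
    if (any(lens != n_peaks)) stop_argument("peak layout vectors must have length n_peaks")
    if (any(peak_amplitude <= 0) || any(sigma_retention <= 0) ||
        any(sigma_drift <= 0)) {
      stop_argument("amplitudes and sigmas must be positive")
    }
  }
  structure(list(n_retention = as.integer(n_retention),
                 n_drift = as.integer(n_drift),
                 retention = retention, drift = drift,
                 rip_drift_index = as.integer(rip_drift_index),
                 rip_intensity = rip_intensity,
                 n_peaks = as.integer(n_peaks),
                 peak_retention = peak_retention, peak_drift = peak_drift,
                 peak_amplitude = peak_amplitude,
                 sigma_retention = sigma_retention, sigma_drift = sigma_drift,
                 amp_jitter_sd = amp_jitter_sd,
                 baseline_noise_sd = baseline_noise_sd,
                 layout_seed = as.integer(layout_seed)),
            class = "spectrum_sim_params")
}

#' Generate one synthetic GC-IMS spectrum
#'
#' Intensities are Gaussian baseline noise, plus a constant vertical RIP
#' column, plus the sum of 2D Gaussian peaks with per-sample log-normal
#' amplitude jitter. For `class_label = 1` the base amplitudes of
#' `effect_peaks` are multiplied by `effect_size`. Negative values are
#' clipped to 0. Deterministic given `seed`.
#'
#' @param params A [spectrum_sim_params()].
#' @param class_label 0 or 1.
#' @param effect_peaks Integer indices of class-affected peaks.
#' @param effect_size Multiplicative amplitude shift for the positive class
#'   (1 = no effect).
#' @param seed Per-sample seed.
#' @param sample_id Sample identifier.
#' @param amp_multiplier Optional extra multiplier on all peak amplitudes
#'   (used for patient-level random effects).
#' @return An [ims_spectrum()].
#' @export
generate_spectrum <- function(params, class_label = 0L,
                              effect_peaks = integer(0), effect_size = 1,
                              seed = 1L, sample_id = "sim",
                              amp_multiplier = 1) {
  if (!inherits(params, "spectrum_sim_params")) {
    stop_argument("params must be spectrum_sim_params")
  }
  if (length(effect_peaks) &&
      (any(effect_peaks < 1L) || any(effect_peaks > params$n_peaks))) {
    stop_argument("effect peak index out of range")
  }
  nr <- params$n_retention; nd <- params$n_drift
  draws <- with_seed(seed, list(
    noise = if (params$baseline_noise_sd > 0) {
      matrix(stats::rnorm(nr * nd, sd = params$baseline_noise_sd), nr, nd)
    } else matrix(0, nr, nd),
    jitter = if (params$n_peaks > 0L) {
      stats::rlnorm(params$n_peaks, 0, params$amp_jitter_sd)
    } else numeric(0)))
  M <- draws$noise
  M[, params$rip_drift_index] <- M[, params$rip_drift_index] + params$rip_intensity
  if (params$n_peaks > 0L) {
    amps <- params$peak_amplitude * draws$jitter * amp_multiplier
    if (class_label == 1L && length(effect_peaks)) {
      amps[effect_peaks] <- amps[effect_peaks] * effect_size
    }
    Er <- exp(-outer(params$retention, params$peak_retention, "-")^2 /
                rep(2 * params$sigma_retention^2, each = nr))
    Ed <- exp(-outer(params$peak_drift, params$drift, "-")^2 /
                (2 * params$sigma_drift^2))
    M <- M + Er %*% (amps * Ed)
  }
  M[M < 0] <- 0
  ims_spectrum(sample_id, params$retention, params$drift, M)
}

#' Simulation parameters for an obstetric cohort
#'
#' Defaults mirror a high-risk preterm prevention clinic population:
#' 216 patients, 12% BV prevalence, 20% preterm prevalence among known
#' spontaneous deliveries, 59% preterm risk given BV, and exclusion-sized
#' fractions of iatrogenic (11/216) and unknown-delivery (9/216) patients.
#' Preterm deliveries fall into midtrimester / extreme / very / late
#' categories with weights 2 : 6 : 10 : 21; term deliveries are a
#' discretised normal centred at 39 + 3 weeks (sd 9 days) truncated at
#' 37 + 0.
#'
#' @param n_patients Cohort size.
#' @param bv_prevalence,preterm_prevalence,p_preterm_given_bv Joint law of
#'   BV and spontaneous preterm delivery; the implied P(preterm | no BV)
#'   must land in `[0, 1]`.
#' @param iatrogenic_rate,unknown_rate Fractions of patients with an
#'   iatrogenic preterm delivery or missing delivery data.
#' @param swabs_per_patient Integer range, e.g. `c(2, 3)`.
#' @param sampling_window_weeks Gestational sampling window (weeks).
#' @param effect_endpoint Which endpoint drives the spectral class effect:
#'   `"preterm"`, `"bv"` or `"none"`.
#' @param effect_peaks Peak indices whose amplitude shifts with the class;
#'   `NULL` (default) uses the first 10 peaks (or all, if fewer).
#' @param effect_size Multiplicative amplitude shift (1 = null cohort).
#' @param patient_effect_sd Log-normal sd of an optional patient-level
#'   random effect on all peak amplitudes (0 = off).
#' @param spectrum Spectrum parameters, a [spectrum_sim_params()].
#' @param seed Master seed; all sub-draws derive from it.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 216L,
                              bv_prevalence = 0.12,
                              preterm_prevalence = 0.20,
                              p_preterm_given_bv = 0.59,
                              iatrogenic_rate = 11 / 216,
                              unknown_rate = 9 / 216,
                              swabs_per_patient = c(2L, 3L),
                              sampling_window_weeks = c(10, 29),
                              effect_endpoint = c("preterm", "bv", "none"),
                              effect_peaks = NULL,
                              effect_size = 2,
                              patient_effect_sd = 0,
                              spectrum = spectrum_sim_params(),
                              seed = 1L) {
  effect_endpoint <- match.arg(effect_endpoint)
  probs <- c(bv_prevalence, preterm_prevalence, p_preterm_given_bv,
             iatrogenic_rate, unknown_rate)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must be in [0, 1]")
  p_no_bv <- (preterm_prevalence - bv_prevalence * p_preterm_given_bv) /
    (1 - bv_prevalence)
  if (p_no_bv < 0 || p_no_bv > 1) {
    stop_config(sprintf(
      "implied P(preterm | BV negative) = %.3f lies outside [0, 1]", p_no_bv))
  }
  if (!is_count(n_patients, 1L)) stop_config("n_patients must be a positive integer")
  if (is.null(effect_peaks)) {
    effect_peaks <- seq_len(min(10L, spectrum$n_peaks))
  }
  if (length(effect_peaks) &&
      (any(effect_peaks < 1L) || any(effect_peaks > spectrum$n_peaks))) {
    stop_config("effect_peaks indices exceed the spectrum peak count")
  }
  structure(list(n_patients = as.integer(n_patients),
                 bv_prevalence = bv_prevalence,
                 preterm_prevalence = preterm_prevalence,
                 p_preterm_given_bv = p_preterm_given_bv,
                 p_preterm_given_no_bv = p_no_bv,
                 iatrogenic_rate = iatrogenic_rate,
                 unknown_rate = unknown_rate,
                 swabs_per_patient = as.integer(swabs_per_patient),
                 sampling_window_weeks = sampling_window_weeks,
                 effect_endpoint = effect_endpoint,
                 effect_peaks = as.integer(effect_peaks),
                 effect_size = effect_size,
                 patient_effect_sd = patient_effect_sd,
                 spectrum = spectrum,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

# Preterm delivery-category weights (midtrimester : extreme : very : late)
# and day ranges used by the cohort generator.
PRETERM_CATEGORY_WEIGHTS <- c(2, 6, 10, 21)
PRETERM_CATEGORY_RANGES <- list(c(140L, 167L), c(168L, 195L),
                                c(196L, 223L), c(224L, 258L))

draw_delivery_days <- function(preterm) {
  if (preterm) {
    cat <- sample.int(4L, 1L, prob = PRETERM_CATEGORY_WEIGHTS)
    rg <- PRETERM_CATEGORY_RANGES[[cat]]
    sample(seq.int(rg[1], rg[2]), 1L)
  } else {
    repeat {
      d <- round(stats::rnorm(1, mean = 39 * 7 + 3, sd = 9))
      if (d >= PRETERM_CUTOFF_DAYS && d <= 42 * 7) return(as.integer(d))
    }
  }
}

#' Generate a synthetic obstetric cohort with GC-IMS spectra
#'
#' Per patient: BV and spontaneous-preterm status are drawn from the joint
#' law implied by the prevalences; a fraction of patients are instead
#' given iatrogenic deliveries or missing delivery data; delivery gestation
#' comes from the category-conditional distributions; swab gestations are
#' uniform in the sampling window (kept at least a week before a known
#' delivery) and sorted; one spectrum is generated per swab, with the
#' class effect applied when the patient is positive for
#' `params$effect_endpoint`. Deterministic given `params$seed`.
#'
#' @param params A [cohort_sim_params()].
#' @return List with `patients`, `swabs` data frames, `spectra` (named list
#'   of [ims_spectrum()] keyed by sample id) and `params`.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_sim_params")) {
    stop_argument("params must be cohort_sim_params")
  }
  n <- params$n_patients
  seeds <- derive_seeds(params$seed, 2L)
  sw <- params$sampling_window_weeks
  win_lo <- as.integer(round(sw[1] * 7)); win_hi <- as.integer(round(sw[2] * 7))

  cohort <- with_seed(seeds[1], {
    bv <- stats::runif(n) < params$bv_prevalence
    status_u <- stats::runif(n)
    outcome <- ifelse(status_u < params$iatrogenic_rate, "iatrogenic",
                      ifelse(status_u < params$iatrogenic_rate + params$unknown_rate,
                             "unknown", "spontaneous"))
    p_pt <- ifelse(bv, params$p_preterm_given_bv, params$p_preterm_given_no_bv)
    preterm <- outcome == "spontaneous" & stats::runif(n) < p_pt
    delivery <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (outcome[i] == "spontaneous") {
        delivery[i] <- draw_delivery_days(preterm[i])
      } else if (outcome[i] == "iatrogenic") {
        delivery[i] <- sample(seq.int(200L, 258L), 1L)
      }
    }
    n_swabs <- sample(seq.int(params$swabs_per_patient[1],
                              params$swabs_per_patient[2]),
                      n, replace = TRUE)
    pat_mult <- if (params$patient_effect_sd > 0) {
      stats::rlnorm(n, 0, params$patient_effect_sd)
    } else rep(1, n)
    age <- round(stats::rnorm(n, 31, 5), 1)
    bmi <- round(stats::rlnorm(n, log(26), 0.18), 1)
    smoking <- sample(c("yes", "no", "unknown"), n, replace = TRUE,
                      prob = c(0.12, 0.80, 0.08))
    list(bv = bv, outcome = outcome, preterm = preterm, delivery = delivery,
         n_swabs = n_swabs, pat_mult = pat_mult, age = age, bmi = bmi,
         smoking = smoking)
  })

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_years = cohort$age, bmi = cohort$bmi,
    ethnicity = NA_character_, smoking = cohort$smoking,
    indication = NA_character_,
    outcome = cohort$outcome, delivery_days = cohort$delivery,
    stringsAsFactors = FALSE)

  swab_seeds <- derive_seeds(seeds[2], n)
  swab_rows <- vector("list", n)
  spectra <- list()
  for (i in seq_len(n)) {
    hi <- win_hi
    if (!is.na(cohort$delivery[i])) hi <- min(hi, cohort$delivery[i] - 7L)
    hi <- max(hi, win_lo)
    k <- cohort$n_swabs[i]
    sub <- derive_seeds(swab_seeds[i], k + 1L)
    gest <- with_seed(sub[k + 1L],
                      sort(sample(seq.int(win_lo, hi), k, replace = FALSE)))
    positive <- switch(params$effect_endpoint,
                       preterm = isTRUE(cohort$preterm[i]),
                       bv = isTRUE(cohort$bv[i]),
                       none = FALSE)
    ids <- sprintf("%s_S%d", patients$patient_id[i], seq_len(k))
    for (j in seq_len(k)) {
      spectra[[ids[j]]] <- generate_spectrum(
        params$spectrum,
        class_label = as.integer(positive),
        effect_peaks = params$effect_peaks,
        effect_size = params$effect_size,
        seed = sub[j], sample_id = ids[j],
        amp_multiplier = cohort$pat_mult[i])
    }
    swab_rows[[i]] <- data.frame(
      patient_id = patients$patient_id[i], sample_id = ids,
      gestation_days = gest,
      bv_status = if (cohort$bv[i]) "positive" else "negative",
      stringsAsFactors = FALSE)
  }
  swabs <- do.call(rbind, swab_rows)
  gest_weeks <- swabs$gestation_days / 7
  if (any(gest_weeks < 10 | gest_weeks >= 30)) {
    warning("some swab gestations fall outside the 10-29 week sampling window",
            call. = FALSE)
  }
  list(patients = patients, swabs = swabs, spectra = spectra, params = params)
}

#' Write a simulated cohort to disk
#'
#' Writes `patients.csv`, `swabs.csv` and one spectrum text file per swab
#' (gestations serialised as "W + D").
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param write_spectra Also write the per-swab spectrum files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_spectra = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pts <- cohort$patients
  pts$delivery_gestation <- format_gestation(pts$delivery_days)
  utils::write.csv(pts, file.path(dir, "patients.csv"), row.names = FALSE)
  sw <- cohort$swabs
  sw$gestation <- format_gestation(sw$gestation_days)
  utils::write.csv(sw, file.path(dir, "swabs.csv"), row.names = FALSE)
  if (write_spectra) {
    spdir <- file.path(dir, "spectra")
    dir.create(spdir, showWarnings = FALSE)
    for (id in names(cohort$spectra)) {
      write_spectrum(cohort$spectra[[id]], file.path(spdir, paste0(id, ".txt")))
    }
  }
  invisible(dir)
}
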