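# Obstetric cohort data model and summaries: gestational-age arithmetic in
# "weeks + days" notation, delivery categorisation, per-patient analysis
# swab selection, analysis-set construction with the exclusion rules for
# iatrogenic and unknown deliveries, cohort rate summaries, and
# normality-gated two-group comparisons.
#
# Cohort tables are plain data frames:
#   patients: patient_id, age_years, bmi, ethnicity, smoking, indication,
#             outcome ("spontaneous" | "iatrogenic" | "unknown"),
#             delivery_days (NA when unknown)
#   swabs:    patient_id, sample_id, gestation_days,
#             bv_status ("positive" | "negative" | "untested")

PRETERM_CUTOFF_DAYS <- 37L * 7L   # before 37 + 0 weeks
VERY_PRETERM_CUTOFF_DAYS <- 32L * 7L

#' Parse "weeks + days" gestational-age notation
#'
#' @param text Character vector like `"17 + 4"` (whitespace optional);
#'   days must be in 0..6.
#' @return Integer vector of total days.
#' @export
#' @examples
#' parse_gestation("17 + 4")  # 123
parse_gestation <- function(text) {
  m <- regmatches(text, regexec("^\\s*(\\d+)\\s*\\+\\s*(\\d+)\\s*$", text))
  vapply(seq_along(text), function(i) {
    g <- m[[i]]
    if (length(g) != 3L) {
      stop_format(sprintf("cannot parse gestation '%s' (expected 'W + D')", text[i]))
    }
    w <- as.integer(g[2]); d <- as.integer(g[3])
    if (d > 6L) {
      stop_format(sprintf("gestation '%s': days component must be 0..6", text[i]))
    }
    7L * w + d
  }, integer(1))
}

#' Render gestational days as "W + D"
#'
#' @param days Numeric vector of gestational days; fractional values are
#'   rounded to the nearest day.
#' @return Character vector in `"W + D"` notation.
#' @export
format_gestation <- function(days) {
  d <- as.integer(round(days))
  if (any(d < 0, na.rm = TRUE)) stop_argument("gestational days must be >= 0")
  ifelse(is.na(d), NA_character_, sprintf("%d + %d", d %/% 7L, d %% 7L))
}

DELIVERY_CATEGORIES <- c("midtrimester_miscarriage", "extreme_preterm",
                         "very_preterm", "late_preterm", "term")

#' Categorise a delivery by gestational age
#'
#' Boundaries: < 24+0 midtrimester miscarriage; 24+0 to < 28+0 extreme
#' preterm; 28+0 to 31+6 very preterm; 32+0 to 36+6 late preterm; >= 37+0
#' term. The preterm/term binary used throughout the analyses is simply
#' "category != term", i.e. delivery before 37 + 0 weeks.
#'
#' @param days Gestational age at delivery in days.
#' @return Factor with the five delivery categories.
#' @export
categorize_delivery <- function(days) {
  if (any(days < 0, na.rm = TRUE)) stop_argument("gestational days must be >= 0")
  cut(days, breaks = c(-Inf, 24 * 7 - 0.5, 28 * 7 - 0.5, 32 * 7 - 0.5,
                       37 * 7 - 0.5, Inf),
      labels = DELIVERY_CATEGORIES, right = TRUE)
}

#' Is a delivery preterm (before 37 + 0 weeks)?
#'
#' @param days Gestational age at delivery in days.
#' @return Logical vector.
#' @export
is_preterm <- function(days) days < PRETERM_CUTOFF_DAYS

#' Select a patient's analysis swab
#'
#' `"first"` picks the swab at the earliest sampling gestation; that is the
#' midtrimester prediction setting. `"closest_to_delivery"` picks the swab
#' minimising (delivery gestation - sampling gestation), i.e. the latest
#' swab. Ties are broken by earlier position in the stored order.
#'
#' @param swabs Data frame of one patient's swabs (columns `sample_id`,
#'   `gestation_days`, ...).
#' @param mode `"first"` or `"closest_to_delivery"`.
#' @param delivery_days Gestation at delivery (required for
#'   `"closest_to_delivery"`).
#' @return The selected swab row (one-row data frame).
#' @export
select_analysis_swab <- function(swabs, mode = c("first", "closest_to_delivery"),
                                 delivery_days = NULL) {
  mode <- match.arg(mode)
  if (nrow(swabs) == 0L) stop_degenerate("patient has no swabs")
  if (mode == "first") {
    swabs[which.min(swabs$gestation_days), , drop = FALSE]
  } else {
    if (is.null(delivery_days) || is.na(delivery_days)) {
      stop_argument("closest_to_delivery requires a known delivery gestation")
    }
    swabs[which.min(delivery_days - swabs$gestation_days), , drop = FALSE]
  }
}

patient_bv_positive <- function(patients, swabs) {
  pos <- tapply(swabs$bv_status == "positive", swabs$patient_id, any)
  unname(pos[match(patients$patient_id, names(pos))]) %in% TRUE
}

#' Build an analysis set: one labelled sample per patient
#'
#' For the preterm endpoint, patients with an iatrogenic delivery or with
#' no delivery data are excluded, and the label is delivery before 37 + 0
#' weeks. For the BV endpoint all patients are eligible and the label is a
#' BV-positive result on any swab during pregnancy. One swab per patient is
#' chosen via [select_analysis_swab()].
#'
#' @param patients,swabs Cohort data frames (see file header).
#' @param endpoint `"bv"` or `"preterm"`.
#' @param swab_mode Passed to [select_analysis_swab()].
#' @return Data frame with `patient_id`, `sample_id`, `label`.
#' @export
build_analysis_set <- function(patients, swabs, endpoint = c("bv", "preterm"),
                               swab_mode = c("first", "closest_to_delivery")) {
  endpoint <- match.arg(endpoint)
  swab_mode <- match.arg(swab_mode)
  if (endpoint == "preterm") {
    keep <- patients$outcome == "spontaneous" & !is.na(patients$delivery_days)
    pts <- patients[keep, , drop = FALSE]
    labels <- as.integer(is_preterm(pts$delivery_days))
  } else {
    pts <- patients
    labels <- as.integer(patient_bv_positive(pts, swabs))
  }
  if (swab_mode == "closest_to_delivery") {
    ok <- !is.na(pts$delivery_days)
    pts <- pts[ok, , drop = FALSE]; labels <- labels[ok]
  }
  if (nrow(pts) == 0L) stop_degenerate("analysis set is empty")
  chosen <- lapply(seq_len(nrow(pts)), function(i) {
    sw <- swabs[swabs$patient_id == pts$patient_id[i], , drop = FALSE]
    select_analysis_swab(sw, swab_mode, pts$delivery_days[i])
  })
  data.frame(patient_id = pts$patient_id,
             sample_id = vapply(chosen, function(s) s$sample_id, character(1)),
             label = labels,
             stringsAsFactors = FALSE)
}

rate_field <- function(count, n) {
  list(count = as.integer(count), n = as.integer(n),
       pct = if (n > 0) round_half_up(100 * count / n, 1) else NA_real_,
       degenerate = n <= 1L)
}

#' Summarise cohort rates
#'
#' Reports, each as count, denominator and percentage (half-up, one
#' decimal): the BV-positive rate among all patients; the preterm rate
#' among the spontaneous-outcome cohort with known delivery; the rate of
#' delivery before 32 weeks in that cohort; and the preterm rates among
#' BV-positive and BV-negative patients with known spontaneous outcome.
#' Zero or single-count denominators are flagged per field, not fatal.
#'
#' @param patients,swabs Cohort data frames.
#' @return List of rate records (`count`, `n`, `pct`, `degenerate`) plus a
#'   `delivery_categories` count table.
#' @export
summarize_cohort <- function(patients, swabs) {
  if (nrow(patients) < 1L) stop_argument("need at least one patient")
  bv_pos <- patient_bv_positive(patients, swabs)
  spont <- patients$outcome == "spontaneous" & !is.na(patients$delivery_days)
  preterm <- spont & is_preterm(patients$delivery_days)
  before32 <- spont & patients$delivery_days < VERY_PRETERM_CUTOFF_DAYS
  list(
    bv_positive = rate_field(sum(bv_pos), nrow(patients)),
    preterm = rate_field(sum(preterm), sum(spont)),
    delivery_before_32w = rate_field(sum(before32), sum(spont)),
    preterm_given_bv = rate_field(sum(preterm & bv_pos), sum(spont & bv_pos)),
    preterm_given_bv_negative = rate_field(sum(preterm & !bv_pos),
                                           sum(spont & !bv_pos)),
    delivery_categories = table(categorize_delivery(
      patients$delivery_days[spont])))
}

#' Compare a characteristic between two groups
#'
#' Numeric data: Shapiro-Wilk normality is tested in both groups at
#' alpha = 0.05; if both pass, a pooled-variance two-sample t-test is used
#' and mean (SD) reported, otherwise a Mann-Whitney test with median (IQR).
#' Categorical data: chi-square on the contingency table without
#' continuity correction (a warning is raised by the test when expected
#' counts are small). Zero variance in both groups is reported as a
#' degenerate comparison with p = 1.
#'
#' @param values Numeric vector, or character/factor for categorical data.
#' @param groups Two-level grouping vector aligned with `values`.
#' @param type `"auto"` (numeric gate) or `"categorical"`.
#' @return List with `test` (which branch fired), `p`, and per-group
#'   location/scale or count summaries.
#' @export
compare_groups <- function(values, groups, type = c("auto", "categorical")) {
  type <- match.arg(type)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop_argument("need exactly two groups")
  groups <- droplevels(groups)
  if (type == "categorical" || !is.numeric(values)) {
    tab <- table(values, groups)
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(list(test = "chi_square", p = unname(ct$p.value),
                statistic = unname(ct$statistic), table = tab))
  }
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (length(g1) < 3L || length(g2) < 3L) {
    stop_argument("need at least 3 numeric observations per group")
  }
  summaries <- list()
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    return(list(test = "degenerate", p = 1,
                summaries = list(mean = c(mean(g1), mean(g2)))))
  }
  normal <- function(v) stats::sd(v) > 0 && stats::shapiro.test(v)$p.value > 0.05
  if (normal(g1) && normal(g2)) {
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    list(test = "t", p = unname(tt$p.value),
         summaries = list(mean = c(mean(g1), mean(g2)),
                          sd = c(stats::sd(g1), stats::sd(g2))))
  } else {
    p <- mw_test(g1, g2)$p
    q <- rbind(median_iqr(g1), median_iqr(g2))
    list(test = "mann_whitney", p = p,
         summaries = list(median = q[, 1], q1 = q[, 2], q3 = q[, 3]))
  }
}

#' Median and interquartile range
#'
#' Linear-interpolation (type 7) quantiles. For gestational-age data the
#' result can be rendered back to "W + D" text with [format_gestation()].
#'
#' @param values Numeric vector (days for gestational ages).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1L) stop_argument("need at least one value")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE,
                       na.rm = TRUE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Deterministic reference cohort at the published marginal rates
#'
#' A synthetic 216-patient reconstruction of the high-risk preterm
#' prevention clinic population this package models: 26 BV-positive
#' patients, 11 iatrogenic deliveries, 9 with unknown delivery data,
#' leaving 196 with known spontaneous outcome of whom 39 delivered preterm
#' (13 of the 22 BV-positive), with preterm deliveries split 2 / 6 / 10 /
#' 21 across midtrimester / extreme / very / late categories. Patient-level
#' only (no spectra); swab records carry placeholder sampling gestations.
#' Built arithmetically, no randomness.
#'
#' @return List with `patients` and `swabs` data frames.
#' @export
example_cohort <- function() {
  # one row per (bv, outcome block): category deliveries in days
  blocks <- list(
    # bv, outcome, delivery_days vector (NA = unknown), count
    list(bv = TRUE,  outcome = "spontaneous", days = 160, n = 1),   # midtrim
    list(bv = TRUE,  outcome = "spontaneous", days = 182, n = 2),   # extreme
    list(bv = TRUE,  outcome = "spontaneous", days = 210, n = 3),   # very
    list(bv = TRUE,  outcome = "spontaneous", days = 240, n = 7),   # late
    list(bv = TRUE,  outcome = "spontaneous", days = 273, n = 9),   # term
    list(bv = TRUE,  outcome = "iatrogenic",  days = 230, n = 1),
    list(bv = TRUE,  outcome = "unknown",     days = NA,  n = 3),
    list(bv = FALSE, outcome = "spontaneous", days = 160, n = 1),
    list(bv = FALSE, outcome = "spontaneous", days = 182, n = 4),
    list(bv = FALSE, outcome = "spontaneous", days = 210, n = 7),
    list(bv = FALSE, outcome = "spontaneous", days = 240, n = 14),
    list(bv = FALSE, outcome = "spontaneous", days = 273, n = 148),
    list(bv = FALSE, outcome = "iatrogenic",  days = 230, n = 10),
    list(bv = FALSE, outcome = "unknown",     days = NA,  n = 6))
  bv <- unlist(lapply(blocks, function(b) rep(b$bv, b$n)))
  outcome <- unlist(lapply(blocks, function(b) rep(b$outcome, b$n)))
  days <- unlist(lapply(blocks, function(b) rep(b$days, b$n)))
  n <- length(bv)
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = NA_real_, bmi = NA_real_, ethnicity = NA_character_,
    smoking = NA_character_, indication = NA_character_,
    outcome = outcome, delivery_days = days,
    stringsAsFactors = FALSE)
  swabs <- data.frame(
    patient_id = rep(patients$patient_id, each = 2L),
    sample_id = sprintf("S%03d_%d", rep(seq_len(n), each = 2L), 1:2),
    gestation_days = rep(c(12L * 7L, 22L * 7L), n),
    bv_status = ifelse(rep(bv, each = 2L), "positive", "negative"),
    stringsAsFactors = FALSE)
  list(patients = patients, swabs = swabs)
}
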