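---
title: "Predicting bacterial vaginosis and preterm birth from GC-IMS VOC profiles"
author: "vocptb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial vaginosis and preterm birth from GC-IMS VOC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocptb)
```

## The problem and the data

Spontaneous preterm birth — delivery before 37 + 0 weeks' gestation after
spontaneous onset of labour — is the leading cause of death in children
under five, and its multifactorial origins make prediction hard. One
candidate signal is the volatile organic compound (VOC) profile of the
vagina: VOCs reflect both the vaginal microbiota (bacterial vaginosis, BV,
has a characteristic odour) and the host response to it.

A gas chromatograph coupled to an ion mobility spectrometer (GC-IMS)
measures that profile as a dense two-dimensional intensity map: molecules
elute from the GC column at a *retention time* (seconds, the row axis),
are ionised, and traverse the IMS drift tube in a *drift time*
(milliseconds, the column axis). Analytes appear as roughly Gaussian
blobs; the reactant-ion peak (RIP) — the instrument's response when no
analyte is present — appears as a persistent vertical line. A single run
holds millions of cells, almost all of them background.

This package implements the analysis pipeline for such data:

1. **Dimensionality reduction** — one rectangular crop window, chosen once
   and applied identically to every sample, then a background threshold
   that zeroes all cells strictly below a cutoff. Cells of the cropped,
   thresholded grid *are* the features; there is no peak detection or
   alignment.
2. **Class-balanced cross-validation** — the majority class is randomly
   undersampled to the minority size, then samples are split into ten
   stratified folds (90% train / 10% test).
3. **In-fold feature selection** — within each fold, every feature is
   scored by a two-sided Mann-Whitney rank-sum test comparing positive
   and negative *training* samples, and the 100 smallest-p features are
   carried into the classifier.
4. **Classification** — a random forest and a Gaussian process produce an
   out-of-fold probability for every sample.
5. **Evaluation** — ROC/AUC with DeLong 95% CI, an operating point by
   Youden's J, sensitivity and specificity with exact (Clopper-Pearson)
   intervals, PPV, NPV, and a between-group Mann-Whitney p-value on the
   out-of-fold probabilities.

The three study analyses are: BV status from the first swab; preterm
delivery from the first swab taken in pregnancy (earliest gestation per
patient); and preterm delivery from the swab taken closest to delivery.
For the preterm endpoint, patients with an iatrogenic preterm delivery or
missing delivery data are excluded.

## Why in-fold selection is the load-bearing wall

With tens of thousands of features and well under a hundred samples,
selecting "discriminative" features on the *full* dataset before
cross-validation leaks test-label information into the model. The effect
is not subtle: on pure-noise data with 2,000 features and 60 samples, the
leaky variant reaches mean cross-validated AUC well above 0.7 while the
correct in-fold pipeline stays at chance. `run_cv_leaky()` exists solely
to demonstrate this (see `leakage_experiment()`); the real pipeline
re-selects features inside every fold.

Two related choices deserve note:

* **The crop and threshold are *not* per-fold.** They are frozen once
  from inspection of all samples, mirroring the one-time manual selection
  a GC-IMS operator performs. They are label-blind (only intensities are
  used), so they do not leak outcome information.
* **Balancing happens once per analysis, before fold assignment**, not
  per fold. The balancing draw is seed-driven and recorded; repeating a
  run reproduces the same subsample.

## Statistical kernels

**Rank-sum test.** For group sizes up to 8 on both sides the p-value is
exact: conditional on the observed (tie-averaged) ranks, all C(n, n1)
assignments to the positive group are enumerated. Larger groups use the
normal approximation with tie correction and continuity correction — the
same approximation `stats::wilcox.test` uses, against which the package is
tested. Features constant across training samples get p = 1 and rank
last; ties in p are broken by the larger absolute rank-biserial effect,
then by the lower feature index, so selection is fully deterministic.

**AUC and its interval.** The point estimate is the Mann-Whitney
concordance probability (tied pairs count one half). The default interval
is DeLong's asymptotic CI from placement-value variances (verified against
`pROC::ci.auc`); a stratified bootstrap is available behind
`ci_method = "bootstrap"` as a cross-check.

**Binomial intervals.** Sensitivity and specificity carry Clopper-Pearson
exact intervals computed by beta-quantile inversion and verified against
direct binomial-tail summation. Group sizes here are modest (tens), where
exact intervals are the defensible choice.

**Operating point.** The study design reports a single
sensitivity/specificity pair but does not fix a rule for choosing the
cut-point, so the package defaults to the Youden-optimal threshold on the
pooled out-of-fold probabilities (ties broken toward higher specificity)
and also supports a fixed 0.5 via configuration; the threshold used is
always embedded in the report.

**Group comparisons** (cohort tables) follow a normality gate: Shapiro-
Wilk at alpha 0.05 in both groups sends the comparison to a pooled t-test
with mean (SD), otherwise to Mann-Whitney with median (IQR); categorical
characteristics use chi-square without continuity correction. Quantiles
are linear-interpolation (type 7) throughout; the convention matters for
IQR endpoints and is therefore fixed and documented rather than left to
chance.

## The synthetic-data generator

No instrument data ships with the package; every claim its tests make is
made on synthetic data whose structure mirrors what the pipeline assumes:

* a 300 x 200 grid (a desk-scale stand-in for the millions of cells of a
  real run) with unit-variance Gaussian baseline noise;
* a constant-intensity RIP column (analyte depletion of the RIP is not
  modelled);
* 30 analyte peaks as 2D Gaussians whose layout (positions, base
  amplitudes ~ log-normal around 30, widths of a few grid steps) is drawn
  once per parameter set and shared by all samples, with per-sample
  log-normal amplitude jitter (sd 0.15 on the log scale);
* a multiplicative class effect: positive-class samples have the base
  amplitudes of 10 designated peaks multiplied by the effect size
  (default 2). A multiplicative amplitude shift is the simplest mechanism
  the cell-intensity feature space can detect; positional (retention /
  drift) shifts are deliberately not simulated, and real chemical
  identity, humidity and retention physics are out of scope.

The default background threshold for simulated spectra is five noise
standard deviations, which keeps about one pure-noise cell in three
million while retaining peak cores; with the default layout the crop +
threshold reduction in non-zero cells is roughly an order of magnitude —
the instrument-scale figure of two orders applies to the far larger real
grids, not to this desk-scale surrogate.

Cohorts are drawn from the joint law implied by BV prevalence 12%,
preterm prevalence 20% and P(preterm | BV) = 0.59 (implying
P(preterm | no BV) about 0.147), with iatrogenic (11/216) and
unknown-delivery (9/216) fractions matching the exclusion counts of the
population the defaults emulate. Preterm deliveries fall into
midtrimester / extreme / very / late categories with weights 2 : 6 : 10 :
21; term deliveries are a discretised normal centred at 39 + 3 weeks (sd
9 days) truncated at 37 + 0. Swab gestations are uniform over weeks
10-29, kept at least a week before a known delivery. An optional
patient-level log-normal random effect on peak amplitudes exists
(`patient_effect_sd`, default 0) because serial swabs from one patient
are surely correlated in reality; the default keeps it off since no
estimate of that correlation is available.

What passing tests on this generator do show: the pipeline recovers a
planted amplitude effect, stays at chance when there is none, and its
feature selection does not leak. What they cannot show: performance on
real swabs, where the signal chemistry, within-patient correlation and
instrument drift are unknown.

## Numerical and design choices

* **Threshold semantics**: cells strictly below the threshold become 0;
  cells equal to it survive. Chosen for determinism and stated here
  because the convention is otherwise ambiguous.
* **Thresholding zeroes, never deletes**: the feature grid stays
  rectangular and shared across samples, which per-fold selection needs.
  All-zero features are retained and handled by the p = 1 rule.
* **Windows are 0-based, half-open** on both axes, everywhere.
* **Automatic crop**: greedy shrink-from-full — repeatedly trim the edge
  row/column with the least above-threshold mass while the window still
  holds the coverage target (default 99%). Exhaustive search is the test
  oracle on small grids; at full coverage greedy provably returns the
  bounding box of the support.
* **Gaussian process**: implemented as least-squares GP classification —
  an RBF-kernel GP *regression* on the 0/1 labels (noise variance 0.1)
  with the posterior mean clipped to [0, 1] — on features standardised by
  training-fold statistics, with the kernel length scale defaulting to
  the median pairwise training distance. The more common logistic-link
  Laplace approximation shrinks probabilities severely toward 0.5 at the
  fold sizes used here (often into (0.26, 0.74) even for perfectly
  separated data), which cripples threshold-based reporting; the
  least-squares form keeps scores well separated, is deterministic, and
  ranks identically for AUC purposes. Both the length scale and the
  classifier choice are configuration-exposed.
* **Random forest**: 1,000 trees, square-root feature subsampling,
  seed-controlled.
* **Seeds**: one user-facing seed expands into named sub-seeds
  (balancing, fold shuffling, per-fold training, per-sample simulation),
  so adding one consumer of randomness never shifts another's stream, and
  every report embeds its seed and a hash of its settings.
* **Problem sizes** used by the validation scripts and tests: 100
  balanced samples on the default 300 x 200 grid for the null and
  signal-recovery checks (10 and 5 seeds), 60 samples x 2,000 features
  for the leakage demonstration, and one 216-patient cohort for the full
  three-analysis run — sizes at which the statistical behaviour of
  interest (chance-level nulls, recovered signal, leakage inflation) is
  already unambiguous.

## Worked example

```{r example, eval = FALSE}
library(vocptb)

co <- generate_cohort(cohort_sim_params(seed = 20170118))
cfg <- run_config(co$patients, co$swabs, co$spectra, threshold = 5,
                  seed = 20170118)
rep <- run_analysis(cfg)
report_table(rep)
```

The `analysis/` scripts run exactly this, plus the cohort summaries and
the validation experiments, writing their tables under `results/`.

## Known limitations

* The generator targets statistical, not chemical, realism; no claim
  about real-swab performance follows from the synthetic results.
* The BV label in simulated cohorts is patient-level (all of a
  BV-positive patient's swabs are marked positive); swab-level BV
  dynamics are not modelled.
* No hyperparameter tuning, nested CV or probability calibration: the
  design reports one ten-fold pass per classifier, and the package
  follows it.
* PPV and NPV are reported at the balanced prevalence of the analysis
  set, not the clinical prevalence; they are not portable to populations
  with different base rates.
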