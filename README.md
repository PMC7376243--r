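# vocptb

Volatile organic compound (VOC) profiling of vaginal swabs for predicting
bacterial vaginosis (BV) and spontaneous preterm birth.

## What this package is for

Spontaneous preterm birth (delivery before 37 + 0 weeks) is hard to
predict because it is multifactorial. VOCs emitted by a vaginal swab
reflect both the vaginal microbiota and the host response, and can be
measured by gas chromatography - ion mobility spectrometry (GC-IMS): each
swab yields a dense 2D intensity map over GC retention time (s) and IMS
drift time (ms), with analytes as Gaussian-ish blobs and a constant
reactant-ion line.

`vocptb` implements, as tested reusable R code, an analysis pipeline for
such data, aimed at researchers evaluating VOC profiles as a diagnostic
or prognostic marker:

* a documented plain-text export dialect and data model for GC-IMS
  matrices (`read_spectrum()` / `write_spectrum()`);
* dimensionality reduction by a shared rectangular crop and a background
  threshold, flattening cells into a samples x features matrix
  (`suggest_crop_window()`, `build_feature_matrix()`);
* class-balanced, stratified ten-fold cross-validation with **in-fold**
  Mann-Whitney rank-sum selection of the 100 lowest-p features, and two
  classifiers — random forest and Gaussian process — yielding
  out-of-fold probabilities (`balance_classes()`, `run_cv()`);
* diagnostic-test evaluation: AUC with DeLong 95% CI, Youden operating
  point, sensitivity/specificity with Clopper-Pearson exact intervals,
  PPV, NPV, and a between-group rank-sum p-value
  (`performance_report()`);
* obstetric cohort handling: "weeks + days" gestational arithmetic,
  delivery categorisation, analysis-set construction with iatrogenic /
  unknown-delivery exclusions, rate summaries and normality-gated group
  comparisons (`build_analysis_set()`, `summarize_cohort()`,
  `compare_groups()`);
* a synthetic GC-IMS spectrum and cohort generator so the entire
  pipeline is exercisable and testable with no instrument data
  (`generate_cohort()`), plus validation experiments
  (`pipeline_auc()`, `leakage_experiment()`).

The statistic at the core of feature selection and evaluation is the
two-sample Mann-Whitney statistic: for feature ranking its two-sided
p-value (exact by enumeration for group sizes <= 8, normal approximation
with tie correction otherwise), and for evaluation its normalised form —
the concordance probability AUC = P(score_pos > score_neg) + 0.5
P(tie) — with DeLong's placement-value variance for the interval.

## Worked example

The `analysis/` scripts run the full study on a simulated cohort; the
core of it is:

```r
library(vocptb)

co  <- generate_cohort(cohort_sim_params(seed = 20170118))  # 216 patients
cfg <- run_config(co$patients, co$swabs, co$spectra, threshold = 5,
                  seed = 20170118)
rep <- run_analysis(cfg)
report_table(rep)
```

which prints (trimmed):

```
         analysis       classifier n_balanced   auc sensitivity specificity   ppv   npv
1              bv    random_forest         48 0.703       0.500       0.958 0.923 0.657
2              bv gaussian_process         48 0.676       0.542       0.958 0.929 0.676
3   preterm_first    random_forest         58 1.000       1.000       1.000 1.000 1.000
4   preterm_first gaussian_process         58 1.000       1.000       1.000 1.000 1.000
5 preterm_closest    random_forest         58 1.000       1.000       1.000 1.000 1.000
6 preterm_closest gaussian_process         58 1.000       1.000       1.000 1.000 1.000
```

Reading it: the simulated cohort plants a strong multiplicative
amplitude effect (x2 on 10 peaks) tied to the *preterm* endpoint, so both
preterm analyses are recovered essentially perfectly (AUC 1.0 on 58
balanced samples). The BV labels carry no direct spectral effect; the BV
analysis still scores above chance (AUC ~0.7) only because BV and preterm
status are correlated in the simulated cohort (59% preterm risk given
BV). The crop + threshold step reduced non-zero cells by a factor of
~13 on these 300 x 200 grids. Run `analysis/01_simulate_cohort.R` through
`analysis/04_validation_experiments.R` to reproduce these tables under
`results/`, including the validation experiments: null cohorts (no
planted effect) give mean out-of-fold AUC 0.539 over 10 seeds, and on
pure-noise data (2,000 features, 60 samples) whole-dataset feature
selection inflates AUC to 0.99 while the correct in-fold pipeline stays
at 0.44 — the leakage the in-fold design exists to prevent.

A deterministic reference cohort mirroring the clinic population the
defaults emulate is available as `example_cohort()`; its summary
reproduces the marginal rates 12.0% BV, 19.9% preterm, 59.1% preterm
given BV, and 9.2% delivered before 32 weeks.

## Layout

```
R/                 package code (spectrum I/O, preprocessing, modelling,
                   evaluation, cohort, synthetic data, orchestration)
analysis/          numbered driver scripts writing results/
scripts/           acceptance.R (see above)
tests/testthat/    unit, property and study-level tests
vignettes/         methods vignette (model, assumptions, design choices)
```
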