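Package: vocptb
Title: Volatile Organic Compound Profiling of Vaginal Swabs for Bacterial
    Vaginosis and Preterm Birth Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for predicting bacterial vaginosis and
    spontaneous preterm birth from gas chromatography - ion mobility
    spectrometry (GC-IMS) volatile organic compound profiles of vaginal
    swabs. Provides a plain-text data model for 2D GC-IMS intensity
    matrices (retention time by drift time), dimensionality reduction by
    uniform crop and background threshold, class-balanced tenfold
    cross-validation with in-fold Mann-Whitney rank-sum feature selection,
    random-forest and Gaussian-process classifiers, and diagnostic-test
    evaluation (ROC/AUC with DeLong confidence intervals, sensitivity,
    specificity, predictive values with exact binomial intervals).
    Includes a synthetic GC-IMS spectrum and obstetric cohort generator so
    the whole pipeline is exercised without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    kernlab,
    randomForest,
    rlang,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
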