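Package: predstab
Title: Bootstrap Stability Assessment for Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the instability of individual risk predictions from a
    clinical prediction model by refitting the entire model-building strategy
    (including tuning, variable selection and data splitting) in bootstrap
    resamples of the development data. Provides prediction-instability,
    calibration-instability, MAPE, classification-instability and
    decision-curve instability plots; per-individual 95% stability intervals;
    the classification instability index; bootstrap c-statistic distributions;
    subgroup (fairness) stratification; minimum sample-size calculators for
    risk prediction models; and a simulation framework for studying the four
    levels of model stability as a function of development sample size.
    Strategies covered: unpenalized logistic regression, LASSO-penalized
    logistic regression with cross-validated penalty selection, logistic
    regression with uniform heuristic shrinkage, random forests (fixed or
    auto-tuned hyperparameters), and split-sample Platt recalibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    ggplot2,
    jsonlite
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
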