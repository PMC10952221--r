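---
title: "Assessing the stability of clinical prediction models by bootstrapping the model-building strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the stability of clinical prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predstab)
```

## The problem: every developed model is one "example model"

A clinical prediction model estimates an individual's risk of a binary
outcome (death by 30 days after myocardial infarction, say) from predictors
measured at baseline. The model actually published is a single realization
of a random process: had the investigators drawn a different same-size
sample from the same population and applied the same model-building
strategy, they would have obtained a different model — a different *example
model* — making different predictions for the same individuals. When the
development sample is small relative to the complexity of the strategy,
those example models can disagree wildly, and any one of them (including
the published one) is then unreliable, regardless of how well it appears to
perform in its own development data.

predstab quantifies this instability at model development time, using only
the development data, by bootstrapping the *entire* model-building
strategy.

## The bootstrap procedure

Given a development cohort of N participants and a strategy (a recipe that
can be re-executed from scratch on any dataset):

1. Fit the strategy on the cohort; record the original predictions
   $\hat p_i$, $i = 1, \dots, N$.
2. Draw a bootstrap resample of size exactly N, with replacement. The size
   matters: instability is a property of the sample size, so the resample
   must emulate it.
3. Refit the **full** strategy on the resample — including cross-validated
   penalty selection, hyperparameter search and any random
   development/recalibration split, because data-driven tuning is itself a
   source of instability.
4. Predict with the refitted model on the **original** N individuals,
   giving $\hat p_{bi}$.
5. Repeat B times (B ≥ 200 recommended; `run_stability_bootstrap()` warns
   below that).

The B × N matrix $\{\hat p_{bi}\}$ supports all the summaries:

* **MAPE** per individual, $\mathrm{MAPE}_i = \sum_b |\hat p_{bi} - \hat
  p_i| / B$, and its average over individuals
  (`mape_per_individual()`, `average_mape()`). "Error" is understood
  against the bootstrap models as stand-ins for the truth.
* **95% stability intervals**: the 2.5th and 97.5th percentiles of each
  individual's $\hat p_{bi}$, smoothed across individuals against
  $\hat p_i$ with LOESS (`stability_intervals()`). These are *not*
  confidence intervals; they describe model-building variability.
* **Classification instability index**: the proportion of bootstrap models
  classifying an individual on the opposite side of a clinically chosen
  risk threshold from the original model
  (`classification_instability_index()`).
* **c-statistic distribution** across bootstrap models applied to the
  original data (`bootstrap_c_distribution()`).
* **Calibration and decision-curve instability**: the spread of flexible
  calibration curves and of net-benefit curves across bootstrap models
  (`calibration_curve()`, `net_benefit_curve()`,
  `render_instability_plots()`).
* **Subgroup (fairness) reports**: all of the above restricted to, e.g.,
  females and males (`subgroup_stability()`). Bootstrap refits are shared
  and their prediction columns sliced, so subgroup contrasts are not
  confounded by separate resampling noise.

### Replicate failures are information

A resample can be degenerate: no events, perfect separation, a model
chi-squared too small for shrinkage estimation. Such refits are recorded
with their reason and excluded, and the run aborts if more than
`failure_cap` (default 2%) fail — at small N, frequent failures are
themselves evidence that the strategy is unstable at that sample size.
Failures appear verbatim in the serialized report's provenance.

## Strategies implemented

* `strategy_logistic()` — maximum-likelihood logistic regression, all
  predictors forced in. Perfect separation raises an error rather than
  returning silently extreme coefficients: masking instability would
  defeat the purpose.
* `strategy_lasso()` — L1-penalized logistic regression, penalty chosen to
  minimize 10-fold cross-validated deviance (glmnet's `lambda.min`).
* `strategy_uniform_shrinkage()` — logistic regression followed by uniform
  shrinkage of all predictor effects with the heuristic factor
  $S = (\chi^2 - p)/\chi^2$ ($\chi^2$ the model likelihood-ratio
  statistic, p the number of predictor parameters), then re-estimation of
  the intercept against the shrunken linear predictor as an offset so that
  the mean predicted risk equals the observed prevalence
  (calibration-in-the-large is restored exactly, to numerical precision).
  $\chi^2 \le p$ means the shrinkage estimate is not usable and the fit is
  flagged degenerate.
* `strategy_random_forest()` — probability forest (per-tree terminal-leaf
  event fractions averaged over trees), defaults 100 trees, unlimited
  depth, minimum leaf size 1. With `auto_tune = TRUE` the depth and leaf
  size are chosen by seeded 5-fold cross-validated log-loss over a
  documented grid (depth 2/3/5/unlimited × leaf 1/5/10) at *every* refit.
* `strategy_split_recalibrated()` — random split of the cohort into a
  development part and a recalibration part; the base strategy is fit on
  the former and Platt-scaled (one-covariate logistic recalibration on the
  clipped logit risk) on the latter. The split is re-randomized in every
  bootstrap refit, since it is part of the strategy.

## Numerical choices

* **Percentiles** use linear interpolation between order statistics (R
  `quantile` type 7). With B = 100 predictions 0.00, 0.01, …, 0.99 the
  2.5th/97.5th percentiles are 0.02475 and 0.96525.
* **LOESS span** for smoothing interval bounds defaults to 0.5
  (sensible range roughly 0.2–0.8); smoothed bounds are clipped to [0, 1]
  and re-ordered pointwise so lower ≤ upper always holds. Where LOESS
  cannot be fit (tiny or degenerate runs) the raw bounds are linearly
  interpolated instead.
* **Risk clipping** before any logit transform uses [1e-6, 1 − 1e-6];
  tree ensembles emit exact 0/1 risks.
* **Classification tie convention**: risk ≥ threshold is "positive";
  documented and tested (a prediction exactly at the threshold flips
  classification against any prediction just below it).
* **Calibration smoother**: local regression of the 0/1 outcome on the
  risk scale by default, a penalized logistic spline on the logit scale as
  the alternative; the grid is restricted to the 1st–99th percentile of
  the risks to avoid edge extrapolation. Constant risks produce the
  degenerate single-point curve (risk, mean outcome).
* **Net benefit** at threshold $p_t$: $\mathrm{NB} = \mathrm{TP}/N -
  (\mathrm{FP}/N)\, p_t/(1-p_t)$, with treat-all
  $\phi - (1-\phi) p_t/(1-p_t)$ and treat-none 0. Default threshold grid
  0.01–0.50 by 0.01; classification thresholds themselves have **no**
  default, because they are a clinical choice.
* **Seed policy**: one master seed; per-replicate streams are pre-derived
  as a vector indexed by replicate, so replicate b is reproducible
  independently of execution order, and the caller's RNG state is never
  disturbed. Cross-validation fold assignment is re-randomized inside
  every bootstrap refit — fold allocation is part of the strategy.
* **LASSO CV folds** are plain random by default, matching the standard
  implementation of 10-fold cross-validation for penalty selection.
  Stratifying folds by outcome systematically damps the tuning variability
  that the bootstrap is supposed to expose (we measured visibly narrower
  level-1 stability ranges at n = 50 with stratified folds), so
  stratification is applied only as a fallback when plain CV fails
  outright on a degenerate fold, or on explicit request
  (`stratified_cv = TRUE`).

## The four-levels simulation study

`generate_simulation_cohort()` draws from a population with a single real
predictor X ~ Normal(0, variance 4), i.e. standard deviation 2, ten noise
variables Z1..Z10 ~ Normal(0, 1), and true risk expit(X) — overall risk
0.5, c-statistic ≈ 0.86. `run_example_model_study()` repeatedly develops a
model (by default LASSO logistic over the 11 candidates) on a fresh cohort
of `n_dev` and applies it to one fixed large test population, summarizing:

1. the spread of mean estimated risk (level 1);
2. MAPE against the true risks and calibration-vs-truth curves (level 2);
3. mean estimated risk in the low-risk subgroup X < −1 (level 3);
4. the spread of estimated risks for nine tracked individuals whose true
   risks are nearest 0.1, …, 0.9 (level 4 — the tracked rows are the
   closest test-population rows, since no canonical individuals exist).

Instability at every level shrinks as `n_dev` grows; the 2.5th–97.5th
percentile range of mean estimated risk is about (0.42, 0.58) at
n_dev = 100, (0.36, 0.64) at 50, and (0.49, 0.51) at 5000. The test suite
verifies these at the study's full size (1000 repetitions against a
100,000-individual test population for n_dev = 100 and 50; 200 repetitions
against 50,000 for n_dev = 5000 — the large-n condition is computationally
dominated by the per-repetition cross-validated fits, and 200 repetitions
already pin the narrow range well inside the tolerance). Directional
invariants (range width decreasing in n_dev) are checked at reduced sizes.

The related minimum-sample-size calculators are closed-form:
`n_for_overall_risk(0.5, 0.05)` = 385 (estimate the overall risk within
0.05), and `n_for_shrinkage(7, 0.08, 0.9)` = 752 (target heuristic uniform
shrinkage 0.9 with 7 parameters and anticipated Cox–Snell R² 0.08). Both
round up; expected events are reported as round(n × prevalence). Only
these two criteria are implemented; the fuller four-criterion framework
(e.g., targeting a MAPE level directly) is out of scope.

## The synthetic GUSTO-like fixture

The seven-predictor case-study cohort (`generate_gusto_like()`) is an
explicit synthetic fixture emulating an acute-MI 30-day-mortality dataset:
five binary predictors (sex, hypertension, hypotension, tachycardia,
previous MI), age, and an ST-elevation lead count 0–11, with a documented
relative coefficient vector (sex log-odds log(1.15), females vs males).
The intercept and a common coefficient scale are solved numerically on a
fixed 200,000-draw reference sample so the population prevalence is 0.07
and the true-risk c-statistic is 0.8 (both verified at large n in the test
suite). It supports self-consistency and *directional* checks only — for
example, that a default-settings random forest (unlimited depth) has a
higher average MAPE than a depth-3 forest on a 752-participant cohort, and
that the female subgroup's average MAPE exceeds the males' under the
fixture's risk structure. No claim of numerical agreement with the real
GUSTO-I dataset is made or tested; an optional `read_gusto_csv()` loader
maps a real export if one is available.

## What the generators do and do not emulate

Both generators produce idealized data: independent rows, no missingness,
correctly specified (logistic-linear) true risk, predictors with simple
marginal distributions and no collinearity beyond chance. Passing tests
therefore demonstrate that the machinery measures instability correctly
under known conditions — not that any particular real dataset is stable.
Real cohorts add missingness (rejected by `validate_cohort()`, by design:
imputation inside every bootstrap refit is rarely practical and silently
completing the data would mask instability), measurement error, and
distribution shift, all of which tend to make instability worse than the
synthetic setting suggests.

## Known limitations

* Binary outcomes only; no survival or multi-class support.
* Simple with-replacement resampling only (no m-out-of-n or subsampling
  variants); outcome-stratified resampling is available but non-default.
* Variable-inclusion-frequency stability and model-selection-frequency
  estimands are not implemented; the focus is prediction-level stability.
* The auto-tuning grid for forests is a pragmatic default, not a claim
  about any published tuning protocol.
* Exact penalty paths differ across LASSO implementations; coefficient
  equality with other software is not a goal (and is immaterial to the
  stability summaries).

## A worked example

```{r example, eval = FALSE}
co <- generate_gusto_like(752, seed = 44)
run <- run_stability_bootstrap(co, strategy_lasso(), B = 200, seed = 10)
report <- stability_report(run, co$y, thresholds = 0.1,
                           subgroups = co$subgroup)
print(report)
render_instability_plots(run, report, co$y, out_dir = "stability_plots")
write_stability_report(run, report, "stability_report.json")
```

The printed report shows the average MAPE, the per-individual MAPE range,
the original and bootstrap c-statistics, the classification instability at
the chosen threshold, and the per-subgroup averages; the plot directory
holds the six instability figures with their underlying data as CSV.
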