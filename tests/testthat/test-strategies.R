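test_that("unpenalized logistic recovers the closed-form saturated fit", {
  # binary predictor, X=1: 30 events/100, X=0: 10 events/100; the MLE is
  # the empirical log odds ratio and baseline log odds
  co <- binary_cohort(e1 = 30, n1 = 100, e0 = 10, n0 = 100)
  fit <- fit_strategy(strategy_logistic(), co)
  expect_equal(unname(fit$beta["x"]), log((30 / 70) / (10 / 90)),
               tolerance = 1e-6)
  expect_equal(unname(fit$intercept), log(10 / 90), tolerance = 1e-6)
  p <- predict_risk(fit, co)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unique(round(p, 6)), c(0.3, 0.1))
})

test_that("a constant predictor collapses to the intercept-only MLE", {
  d <- data.frame(y = rep(c(1, 0, 0, 0), 10), x = 1)
  co <- validate_cohort(d, outcome = "y")
  fit <- fit_strategy(strategy_logistic(), co)
  expect_equal(unname(fit$beta["x"]), 0)
  expect_equal(predict_risk(fit, co), rep(0.25, 40), tolerance = 1e-8)
  expect_identical(fit$diagnostics$dropped, "x")
})

test_that("perfect separation raises instead of returning a fit", {
  d <- data.frame(y = rep(c(1, 0), each = 20),
                  x = c(rnorm(20, 5), rnorm(20, -5)))
  co <- validate_cohort(d, outcome = "y")
  expect_error(fit_strategy(strategy_logistic(), co), "separation")
})

test_that("fully shrunken LASSO is intercept-only at the prevalence", {
  co <- quick_cohort(100, seed = 3)
  fit <- fit_strategy(strategy_lasso(lambda = Inf), co, seed = 1)
  expect_equal(predict_risk(fit, co), rep(co$prevalence, co$n))
})

test_that("LASSO refits are deterministic under a fixed seed", {
  co <- quick_cohort(150, seed = 8)
  f1 <- fit_strategy(strategy_lasso(), co, seed = 99)
  f2 <- fit_strategy(strategy_lasso(), co, seed = 99)
  expect_identical(f1$diagnostics$lambda, f2$diagnostics$lambda)
  expect_identical(f1$beta, f2$beta)
  f3 <- fit_strategy(strategy_lasso(), co, seed = 100)
  expect_false(identical(f3$diagnostics$lambda, f1$diagnostics$lambda))
})

test_that("LASSO at large n keeps the real predictor dominant", {
  co <- generate_simulation_cohort(5000, seed = 21)
  fit <- fit_strategy(strategy_lasso(), co, seed = 21)
  bx <- fit$beta["X"]
  expect_gt(bx, 0.8)
  expect_lt(bx, 1.1)
  expect_true(all(abs(fit$beta[paste0("Z", 1:10)]) < abs(bx)))
})

test_that("LASSO never beats the MLE on in-sample deviance", {
  dev_of <- function(p, y) -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  for (s in 1:3) {
    co <- quick_cohort(200, seed = s)
    pm <- predict_risk(fit_strategy(strategy_logistic(), co), co)
    pl <- predict_risk(fit_strategy(strategy_lasso(), co, seed = s), co)
    expect_gte(dev_of(pmin(pmax(pl, 1e-12), 1 - 1e-12), co$y),
               dev_of(pmin(pmax(pm, 1e-12), 1 - 1e-12), co$y))
  }
})

test_that("uniform shrinkage follows the heuristic formula and recalibrates the mean", {
  co <- quick_cohort(300, seed = 5)
  mle <- fit_strategy(strategy_logistic(), co)
  fit <- fit_strategy(strategy_uniform_shrinkage(), co)
  d <- fit$diagnostics
  expect_equal(d$S, (d$chi2_model - d$p) / d$chi2_model)
  expect_equal(d$chi2_model, mle$diagnostics$lr_chi2, tolerance = 1e-6)
  expect_lt(d$S, 1)
  # shrunken slopes, same direction
  expect_equal(unname(fit$beta), unname(d$S * mle$beta), tolerance = 1e-8)
  # intercept re-estimation restores calibration-in-the-large
  expect_equal(mean(predict_risk(fit, co)), co$prevalence, tolerance = 1e-8)
})

test_that("shrinkage degenerates when the model explains nothing", {
  d <- data.frame(y = rep(c(1, 0, 0, 0), 10), x = 1)
  co <- validate_cohort(d, outcome = "y")
  expect_error(fit_strategy(strategy_uniform_shrinkage(), co),
               "shrinkage degenerate")
})

test_that("random forests split purely and refit deterministically", {
  d <- data.frame(y = rep(c(1, 0), each = 30), x = rep(c(1, 0), each = 30))
  co <- validate_cohort(d, outcome = "y")
  fit <- fit_strategy(strategy_random_forest(n_trees = 10, max_depth = 1),
                      co, seed = 4)
  expect_equal(predict_risk(fit, co), as.numeric(co$y))

  co2 <- quick_cohort(150, seed = 6)
  f1 <- fit_strategy(strategy_random_forest(max_depth = 3), co2, seed = 7)
  f2 <- fit_strategy(strategy_random_forest(max_depth = 3), co2, seed = 7)
  expect_identical(predict_risk(f1, co2), predict_risk(f2, co2))
})

test_that("auto-tuned forests record their selected hyperparameters", {
  co <- generate_gusto_like(400, seed = 13)
  grid <- expand.grid(max_depth = c(2, 3), min_leaf = c(5, 10))
  fit <- fit_strategy(strategy_random_forest(n_trees = 30, auto_tune = TRUE,
                                             tune_grid = grid), co, seed = 2)
  expect_true(fit$diagnostics$tuned)
  expect_true(fit$diagnostics$max_depth %in% grid$max_depth)
  expect_true(fit$diagnostics$min_leaf %in% grid$min_leaf)
  p <- predict_risk(fit, co)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("split recalibration partitions exactly and re-randomizes", {
  co <- generate_gusto_like(752, seed = 17)
  spec <- strategy_split_recalibrated(
    strategy_random_forest(max_depth = 3), dev_n = 452, recal_n = 300)
  fit <- fit_strategy(spec, co, seed = 31)
  expect_length(fit$dev_idx, 452)
  expect_length(fit$recal_idx, 300)
  expect_length(intersect(fit$dev_idx, fit$recal_idx), 0)
  expect_setequal(c(fit$dev_idx, fit$recal_idx), seq_len(752))
  fit2 <- fit_strategy(spec, co, seed = 32)
  expect_false(identical(fit$dev_idx, fit2$dev_idx))
  expect_error(
    fit_strategy(strategy_split_recalibrated(
      strategy_logistic(), dev_n = 400, recal_n = 300), co),
    "must equal N")
})

test_that("recalibrating a constant base model predicts the holdout prevalence", {
  co <- quick_cohort(200, seed = 19)
  spec <- strategy_split_recalibrated(strategy_lasso(lambda = Inf),
                                      dev_n = 120, recal_n = 80)
  fit <- fit_strategy(spec, co, seed = 5)
  expect_equal(fit$recal_slope, 0)
  p <- unique(round(predict_risk(fit, co), 10))
  expect_length(p, 1)
  expect_equal(p, mean(co$y[fit$recal_idx]), tolerance = 1e-8)
})

test_that("recalibrating a well-calibrated base model is near the identity", {
  co <- generate_simulation_cohort(20000, seed = 23)
  spec <- strategy_split_recalibrated(strategy_logistic(),
                                      dev_n = 10000, recal_n = 10000)
  fit <- fit_strategy(spec, co, seed = 23)
  expect_lt(abs(fit$recal_slope - 1), 0.1)
  expect_lt(abs(fit$recal_intercept), 0.1)
})

test_that("strategy specs round-trip through JSON", {
  specs <- list(
    strategy_logistic(),
    strategy_lasso(cv_folds = 5, stratified_cv = TRUE),
    strategy_uniform_shrinkage(),
    strategy_random_forest(n_trees = 50, max_depth = 3, min_leaf = 5),
    strategy_split_recalibrated(strategy_random_forest(max_depth = 3),
                                dev_n = 452, recal_n = 300))
  for (sp in specs) {
    sp2 <- strategy_from_json(strategy_to_json(sp))
    expect_equal(sp2$kind, sp$kind)
    expect_equal(sp2[setdiff(names(sp2), c("base", "tune_grid"))],
                 sp[setdiff(names(sp), c("base", "tune_grid"))])
  }
})
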