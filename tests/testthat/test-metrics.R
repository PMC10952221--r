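test_that("per-individual MAPE matches hand-computed values", {
  run <- fake_run(p_orig = c(0.5, 0.2, 0.4),
                  P_boot = rbind(c(0.4, 0.1, 0.4),
                                 c(0.6, 0.2, 0.4),
                                 c(0.5, 0.6, 0.4)))
  m <- mape_per_individual(run)
  expect_equal(unname(m), c((0.1 + 0.1 + 0) / 3,
                            (0.1 + 0 + 0.4) / 3,
                            0))
  expect_named(m, c("1", "2", "3"))
})

test_that("average MAPE is exactly the mean of per-individual MAPE", {
  set.seed(10)
  run <- fake_run(runif(4), matrix(runif(20), 5, 4))
  expect_identical(average_mape(run), mean(mape_per_individual(run)))
  # identical bootstrap predictions give zero MAPE
  run0 <- fake_run(c(0.2, 0.8), rbind(c(0.2, 0.8), c(0.2, 0.8)))
  expect_equal(average_mape(run0), 0)
})

test_that("stability intervals use interpolated percentiles and ordered smooth bounds", {
  # an individual with bootstrap predictions 0.00, 0.01, ..., 0.99
  vals <- seq(0, 0.99, by = 0.01)
  run <- fake_run(p_orig = c(0.5, 0.5),
                  P_boot = cbind(vals, rep(0.3, 100)))
  iv <- suppressWarnings(stability_intervals(run))
  expect_equal(iv$individual$lower[1], 0.02475)
  expect_equal(iv$individual$upper[1], 0.96525)
  # constant predictions give a zero-width interval
  expect_equal(iv$individual$lower[2], 0.3)
  expect_equal(iv$individual$upper[2], 0.3)
  expect_error(stability_intervals(run, level = 1.2), "level")

  # smoothed bounds stay ordered and inside [0, 1] on a realistic run
  co <- quick_cohort(150, seed = 31)
  run2 <- suppressWarnings(
    run_stability_bootstrap(co, strategy_logistic(), B = 60, seed = 31,
                            failure_cap = 0.25))
  iv2 <- stability_intervals(run2)
  grid <- seq(0.01, 0.99, by = 0.01)
  lo <- iv2$smooth_fun$lower(grid)
  up <- iv2$smooth_fun$upper(grid)
  expect_true(all(lo <= up))
  expect_true(all(lo >= 0 & up <= 1))
  expect_true(all(iv2$individual$lower <= iv2$individual$upper))
})

test_that("classification instability index follows the >= tie convention", {
  run <- fake_run(p_orig = 0.6,
                  P_boot = matrix(c(0.7, 0.55, 0.4, 0.45), ncol = 1))
  expect_equal(unname(classification_instability_index(run, 0.5)), 0.5)
  # all on the same side: zero instability
  run2 <- fake_run(0.6, matrix(c(0.9, 0.55, 0.51), ncol = 1))
  expect_equal(unname(classification_instability_index(run2, 0.5)), 0)
  # a prediction exactly at the threshold counts as positive
  eps <- 1e-9
  run3 <- fake_run(0.5, matrix(c(0.5, 0.5 - eps), ncol = 1))
  expect_equal(unname(classification_instability_index(run3, 0.5)), 0.5)
  expect_error(classification_instability_index(run, 1.5), "threshold")
})

test_that("c-statistic matches the all-pairs brute-force oracle", {
  brute_c <- function(risks, y) {
    ev <- risks[y == 1]
    ne <- risks[y == 0]
    tot <- 0
    for (a in ev) for (b in ne)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(ev) * length(ne))
  }
  expect_equal(c_statistic(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(c_statistic(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  set.seed(52)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))  # guarantee both classes
    r <- round(runif(n), 2)              # rounding forces ties
    expect_equal(c_statistic(r, y), brute_c(r, y))
  }
  expect_error(c_statistic(c(0.1, 0.2), c(1, 1)), "degenerate")
})

test_that("c-statistic is invariant under strictly increasing transforms", {
  set.seed(3)
  r <- runif(40)
  y <- rbinom(40, 1, r)
  y[1:2] <- c(0, 1)
  expect_equal(c_statistic(qlogis(r), y), c_statistic(r, y))
  expect_equal(c_statistic(r^3, y), c_statistic(r, y))
})

test_that("bootstrap c-statistic distribution degenerates correctly", {
  set.seed(14)
  p <- runif(30)
  y <- rbinom(30, 1, p); y[1:2] <- c(0, 1)
  run <- fake_run(p, rbind(p, p, p))
  cs <- bootstrap_c_distribution(run, y)
  expect_equal(as.vector(cs), rep(c_statistic(p, y), 3))
  s <- attr(cs, "summary")
  expect_equal(unname(s["min"]), unname(s["max"]))
  expect_true(all(cs >= 0 & cs <= 1))
})

test_that("calibration curves track a perfectly calibrated generator", {
  set.seed(6)
  n <- 5000
  r <- runif(n, 0.02, 0.98)
  y <- rbinom(n, 1, r)
  cc <- calibration_curve(r, y)
  on_grid <- cc$grid >= 0.1 & cc$grid <= 0.9
  expect_lt(max(abs(cc$observed[on_grid] - cc$grid[on_grid])), 0.05)
})

test_that("calibration handles degenerate inputs per contract", {
  # all-zero outcomes: the curve hugs zero
  set.seed(7)
  r <- runif(200, 0.01, 0.3)
  cc <- calibration_curve(r, rep(0, 200))
  expect_lt(max(cc$observed), 0.02)
  # constant risks: single point (risk, mean y)
  cc2 <- calibration_curve(rep(0.3, 100), rbinom(100, 1, 0.31))
  expect_true(attr(cc2, "degenerate"))
  expect_equal(nrow(cc2), 1L)
  expect_equal(cc2$grid, 0.3)
  expect_warning(calibration_curve(runif(10), rbinom(10, 1, 0.5)),
                 "fewer than 20")
})

test_that("net benefit matches hand evaluation and its exact identities", {
  # N = 10, threshold 0.2, 2 true positives and 1 false positive
  y <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  r <- c(0.9, 0.8, 0.5, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  nb <- net_benefit_curve(r, y, thresholds = 0.2)
  expect_equal(nb$nb_model, 0.2 - 0.1 * 0.25)
  # treat-all at the prevalence threshold has exactly zero net benefit
  phi <- mean(y)
  nb2 <- net_benefit_curve(r, y, thresholds = phi)
  expect_identical(nb2$nb_treat_all, phi - (1 - phi) * phi / (1 - phi))
  expect_equal(nb2$nb_treat_all, 0)
  # threshold below all risks: model = treat-all = prevalence
  nb3 <- net_benefit_curve(r, y, thresholds = 0.05)
  expect_equal(nb3$nb_model, phi - (1 - phi) * 0.05 / 0.95)
  expect_equal(nb3$nb_model, nb3$nb_treat_all)
  # nobody above threshold: model coincides with treat-none
  nb4 <- net_benefit_curve(r, y, thresholds = 0.95)
  expect_equal(nb4$nb_model, 0)
  # nb_min definition and model bound
  full <- net_benefit_curve(r, y)
  expect_equal(full$nb_min,
               pmin(full$nb_model, full$nb_model - full$nb_treat_all))
  expect_true(all(full$nb_model <= phi + 1e-12))
  expect_error(net_benefit_curve(r, y, thresholds = c(0.2, 1)),
               "thresholds")
})

test_that("subgroup reports slice predictions consistently", {
  co <- quick_cohort(200, seed = 41)
  run <- suppressWarnings(
    run_stability_bootstrap(co, strategy_logistic(), B = 40, seed = 41,
                            failure_cap = 0.25))
  labels <- rep(c("a", "b"), each = 100)
  reps <- subgroup_stability(run, co$y, labels)
  expect_named(reps, c("a", "b"))
  # overall average MAPE is the member-weighted mean of subgroup averages
  w <- table(labels)
  expect_equal(average_mape(run),
               (w[["a"]] * reps$a$average_mape +
                  w[["b"]] * reps$b$average_mape) / sum(w))
  # duplicated individuals give identical subgroup MAPE vectors
  run_dup <- fake_run(rep(run$p_orig[1:5], 2),
                      run$P_boot[, c(1:5, 1:5)])
  labels2 <- rep(c("g1", "g2"), each = 5)
  reps2 <- subgroup_stability(run_dup, rep(co$y[1:5], 2), labels2)
  expect_equal(unname(reps2$g1$mape), unname(reps2$g2$mape))
  # undersized subgroups are excluded with a warning
  expect_warning(
    out <- subgroup_stability(run, co$y, c("solo", rep("rest", 199))),
    "solo")
  expect_named(out, "rest")
})
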