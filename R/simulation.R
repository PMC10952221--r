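#' Generate a cohort from the single-predictor stability-study population
#'
#' The data-generating model used throughout the four-levels-of-stability
#' simulation: one real predictor X ~ Normal(0, sd = 2) (variance 4), ten
#' noise variables Z1..Z10 ~ Normal(0, 1), true event risk
#' expit(X) (logistic model with intercept 0 and coefficient 1), and
#' Y ~ Bernoulli(true risk). The population has true overall risk 0.5 and a
#' c-statistic of about 0.86 based on X.
#'
#' @param n Number of individuals (>= 2).
#' @param seed Seed for the cohort's private RNG stream.
#' @return A `predstab_cohort` with `true_risk` attached and predictors
#'   `X`, `Z1`, ..., `Z10`.
#' @examples
#' co <- generate_simulation_cohort(100, seed = 1)
#' mean(co$true_risk)
#' @export
generate_simulation_cohort <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  with_seed(seed, {
    X <- rnorm(n, 0, 2)
    Z <- matrix(rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("Z", 1:10)))
    tr <- plogis(X)
    y <- rbinom(n, 1L, tr)
    df <- data.frame(y = y, X = X, Z, true_risk = tr, check.names = FALSE)
    # a simulated draw can be degenerate at tiny n; regenerating would bias
    # the study, so surface it
    validate_cohort(df, outcome = "y", true_risk = "true_risk")
  })
}

#' Mean absolute error of estimated risks against true risks
#'
#' The population-level accuracy measure available only in simulation,
#' where the data-generating model defines each individual's true risk:
#' mean over individuals of |estimated - true|.
#'
#' @param estimated Estimated risks.
#' @param true_risk True risks of the same individuals.
#' @return A scalar.
#' @export
true_risk_mape <- function(estimated, true_risk) {
  if (length(estimated) != length(true_risk))
    stop("length mismatch between estimated and true risks", call. = FALSE)
  mean(abs(estimated - true_risk))
}

#' Run the example-model stability study
#'
#' Emulates the thought experiment behind model instability: many
#' investigators each develop a model from their own same-size sample of
#' the same population, and all models are applied to one large fixed test
#' population. Each repetition draws a fresh development cohort of
#' `n_dev`, fits `strategy`, and predicts the shared test population.
#' Four levels of stability are summarized:
#' \enumerate{
#'   \item mean estimated risk per repetition (stability of the model's
#'     overall risk);
#'   \item MAPE against the true risks, plus (optionally) a calibration
#'     curve against truth per repetition;
#'   \item mean estimated risk in the low-risk subgroup X < -1;
#'   \item the estimated risks of nine tracked individuals whose true risks
#'     are nearest 0.1, 0.2, ..., 0.9.
#' }
#'
#' @param n_dev Development sample size per repetition.
#' @param reps Number of repetitions (example models).
#' @param n_test Size of the fixed test population.
#' @param strategy Strategy refit in every repetition (default: LASSO
#'   logistic with 10-fold cross-validated penalty).
#' @param seed Master seed; the test population and every repetition derive
#'   private streams from it.
#' @param test_population Optional pre-built test cohort (from
#'   [generate_simulation_cohort()]) to share across studies.
#' @param calibration If `TRUE`, also collect a calibration-against-truth
#'   curve per repetition (slower).
#' @param failure_cap Maximum tolerated fraction of failed repetitions.
#' @return An object of class `predstab_sim`: vectors `mean_risk`,
#'   `mape_true`, `subgroup_mean_risk` (one entry per successful
#'   repetition), matrix `tracked` (reps x 9, columns named by target true
#'   risk), `tracked_true` (the 9 tracked individuals' true risks),
#'   `calib_curves` (list or NULL), `failures`, `n_dev`, `test_hash` (to
#'   verify the same test population is reused).
#' @export
run_example_model_study <- function(n_dev, reps = 1000, n_test = 100000,
                                    strategy = strategy_lasso(),
                                    seed = 1, test_population = NULL,
                                    calibration = FALSE,
                                    failure_cap = 0.02) {
  stopifnot(reps >= 1, n_test >= n_dev)
  seeds <- derive_seeds(seed, reps + 1L)
  test <- test_population %||%
    generate_simulation_cohort(n_test, seed = seeds[reps + 1L])

  # level-4 tracked individuals: test rows with true risk nearest 0.1..0.9
  targets <- seq(0.1, 0.9, by = 0.1)
  tracked_idx <- vapply(targets, function(t)
    which.min(abs(test$true_risk - t)), integer(1))

  mean_risk <- rep(NA_real_, reps)
  mape_true <- rep(NA_real_, reps)
  sub_mean <- rep(NA_real_, reps)
  tracked <- matrix(NA_real_, reps, length(targets),
                    dimnames = list(NULL, format(targets)))
  calib <- if (calibration) vector("list", reps) else NULL
  fail_idx <- integer(0)
  fail_reason <- character(0)
  low_risk <- test$X[, "X"] < -1

  for (r in seq_len(reps)) {
    res <- with_seed(seeds[r], {
      dev_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      fit_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      tryCatch({
        dev <- generate_simulation_cohort(n_dev, seed = dev_seed)
        fit <- fit_strategy(strategy, dev, seed = fit_seed)
        list(p = predict_risk(fit, test))
      }, error = function(e) list(error = conditionMessage(e)))
    })
    if (!is.null(res$error)) {
      fail_idx <- c(fail_idx, r)
      fail_reason <- c(fail_reason, res$error)
      next
    }
    p <- res$p
    mean_risk[r] <- mean(p)
    mape_true[r] <- true_risk_mape(p, test$true_risk)
    sub_mean[r] <- mean(p[low_risk])
    tracked[r, ] <- p[tracked_idx]
    if (calibration)
      calib[[r]] <- calibration_curve(p, test$true_risk,
                                      grid = seq(0.05, 0.95, by = 0.05))
  }

  if (length(fail_idx) / reps > failure_cap)
    stop(sprintf(
      "example-model study aborted: %d/%d repetitions failed; dominant reason: %s",
      length(fail_idx), reps,
      names(sort(table(fail_reason), decreasing = TRUE))[1L]), call. = FALSE)

  ok <- setdiff(seq_len(reps), fail_idx)
  structure(
    list(mean_risk = mean_risk[ok],
         mape_true = mape_true[ok],
         subgroup_mean_risk = sub_mean[ok],
         tracked = tracked[ok, , drop = FALSE],
         tracked_true = test$true_risk[tracked_idx],
         calib_curves = if (calibration) calib[ok] else NULL,
         failures = data.frame(repetition = fail_idx, reason = fail_reason),
         n_dev = n_dev, n_test = test$n, reps = reps,
         strategy = strategy, master_seed = seed,
         test_hash = sum(test$X[, "X"]) + sum(test$y)),
    class = "predstab_sim")
}

#' @export
print.predstab_sim <- function(x, ...) {
  q <- quantile(x$mean_risk, c(0.025, 0.975), type = 7, names = FALSE)
  cat(sprintf("<predstab_sim>  n_dev = %d, %d/%d repetitions, test n = %d\n",
              x$n_dev, length(x$mean_risk), x$reps, x$n_test))
  cat(sprintf("  mean estimated risk: 2.5th-97.5th pct %.3f-%.3f\n",
              q[1L], q[2L]))
  cat(sprintf("  MAPE vs true risks: median %.4f\n", median(x$mape_true)))
  invisible(x)
}

#' Percentile range of mean estimated risk across example models
#'
#' Convenience accessor for the level-1 stability summary.
#'
#' @param sim A `predstab_sim`.
#' @param probs Percentile pair (default 2.5th and 97.5th).
#' @return Named numeric vector of the requested percentiles.
#' @export
mean_risk_range <- function(sim, probs = c(0.025, 0.975)) {
  stopifnot(inherits(sim, "predstab_sim"))
  quantile(sim$mean_risk, probs, type = 7)
}
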