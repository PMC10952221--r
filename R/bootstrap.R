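#' Bootstrap instability assessment of a model-building strategy
#'
#' The core resampling procedure: fit the strategy once on the development
#' cohort to obtain the original predictions, then, B times, draw a
#' with-replacement resample of the same size N, refit the *full* strategy
#' on it (cross-validated tuning, hyperparameter search and random splits
#' included) and predict on the original N individuals. The resulting B x N
#' prediction matrix is the raw material for every instability metric and
#' plot.
#'
#' Replicates whose refit fails (e.g., a degenerate resample with no events,
#' or perfect separation) are recorded and excluded; such failures are
#' themselves evidence of instability and are reported. If more than
#' `failure_cap` of the replicates fail, the run aborts.
#'
#' Each replicate uses a private RNG stream derived from `seed` and the
#' replicate index, so results are reproducible and independent of execution
#' order.
#'
#' @param cohort A [validate_cohort()] cohort.
#' @param spec A strategy from [strategy_logistic()] and friends.
#' @param B Number of bootstrap replicates; at least 200 is recommended for
#'   stable 95% stability intervals (a warning is issued below that).
#' @param seed Master seed.
#' @param failure_cap Maximum tolerated fraction of failed replicates.
#' @param stratified If `TRUE`, resample separately within events and
#'   non-events (non-default; plain resampling preserves fidelity to the
#'   sampling process being emulated).
#'
#' @return An object of class `predstab_run`: `p_orig` (length-N original
#'   predictions), `P_boot` (B_ok x N matrix of bootstrap-model predictions
#'   on the original rows), `B` (successful replicates), `B_requested`,
#'   `failures` (data.frame of replicate index + reason), `per_replicate`
#'   (list of per-fit diagnostics), `ids`, `master_seed`, `spec`.
#'
#' @examples
#' co <- generate_simulation_cohort(150, seed = 7)
#' run <- run_stability_bootstrap(co, strategy_logistic(), B = 50, seed = 7)
#' average_mape(run)
#' @export
run_stability_bootstrap <- function(cohort, spec, B = 200, seed = 1,
                                    failure_cap = 0.02, stratified = FALSE) {
  if (!inherits(cohort, "predstab_cohort"))
    stop("`cohort` must come from validate_cohort()", call. = FALSE)
  stopifnot(inherits(spec, "predstab_strategy"))
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  if (B < 200)
    warning("B < 200 bootstrap replicates; stability intervals may be unreliable",
            call. = FALSE)
  N <- cohort$n

  seeds <- derive_seeds(seed, B + 1L)
  orig_fit <- fit_strategy(spec, cohort, seed = seeds[B + 1L])
  p_orig <- predict_risk(orig_fit, cohort)

  P_boot <- matrix(NA_real_, B, N)
  prov <- vector("list", B)
  fail_idx <- integer(0)
  fail_reason <- character(0)

  for (b in seq_len(B)) {
    res <- with_seed(seeds[b], {
      idx <- if (stratified) {
        c(sample(which(cohort$y == 1L), sum(cohort$y == 1L), replace = TRUE),
          sample(which(cohort$y == 0L), sum(cohort$y == 0L), replace = TRUE))
      } else {
        sample.int(N, N, replace = TRUE)
      }
      fit_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      tryCatch({
        bfit <- fit_strategy(spec, cohort_subset(cohort, idx), seed = fit_seed)
        list(p = predict_risk(bfit, cohort), diag = bfit$diagnostics)
      }, error = function(e) list(error = conditionMessage(e)))
    })
    if (!is.null(res$error)) {
      fail_idx <- c(fail_idx, b)
      fail_reason <- c(fail_reason, res$error)
    } else {
      P_boot[b, ] <- res$p
      prov[[b]] <- res$diag
    }
  }

  if (length(fail_idx) / B > failure_cap) {
    dominant <- names(sort(table(fail_reason), decreasing = TRUE))[1L]
    stop(sprintf(
      "bootstrap aborted: %d/%d replicates failed (cap %.1f%%); dominant reason: %s",
      length(fail_idx), B, 100 * failure_cap, dominant), call. = FALSE)
  }

  ok <- setdiff(seq_len(B), fail_idx)
  structure(
    list(p_orig = as.vector(p_orig),
         P_boot = P_boot[ok, , drop = FALSE],
         B = length(ok), B_requested = B,
         failures = data.frame(replicate = fail_idx, reason = fail_reason),
         per_replicate = prov[ok],
         ids = cohort$ids,
         master_seed = seed,
         spec = spec,
         original_fit = orig_fit),
    class = "predstab_run")
}

#' @export
print.predstab_run <- function(x, ...) {
  cat(sprintf("<predstab_run>  strategy: %s\n", x$spec$kind))
  cat(sprintf("  N = %d individuals, B = %d/%d successful replicates\n",
              length(x$p_orig), x$B, x$B_requested))
  if (nrow(x$failures))
    cat(sprintf("  failures: %d (%s)\n", nrow(x$failures),
                paste(unique(x$failures$reason), collapse = "; ")))
  cat(sprintf("  average MAPE = %.4f\n", average_mape(x)))
  invisible(x)
}

# Restrict a run to a subset of individuals (columns); bootstrap refits are
# not redone — predictions are sliced. Used for subgroup reports.
run_subset_individuals <- function(run, idx) {
  structure(
    list(p_orig = run$p_orig[idx],
         P_boot = run$P_boot[, idx, drop = FALSE],
         B = run$B, B_requested = run$B_requested,
         failures = run$failures,
         per_replicate = run$per_replicate,
         ids = run$ids[idx],
         master_seed = run$master_seed,
         spec = run$spec,
         original_fit = run$original_fit),
    class = "predstab_run")
}

#' Persist the bootstrap prediction matrix for audit
#'
#' Writes one CSV with a `replicate` column (0 = original model) and one
#' column per individual, so the complete set of original and bootstrap
#' predictions lives in a single flat file.
#'
#' @param run A `predstab_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_predictions <- function(run, path) {
  stopifnot(inherits(run, "predstab_run"))
  M <- rbind(run$p_orig, run$P_boot)
  df <- data.frame(replicate = c(0L, seq_len(run$B)), M, check.names = FALSE)
  names(df) <- c("replicate", run$ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
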