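# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal bootstrap-run object with known predictions, for metric tests
# that need exact control over p_orig and P_boot.
fake_run <- function(p_orig, P_boot, ids = NULL) {
  P_boot <- matrix(P_boot, ncol = length(p_orig))
  structure(
    list(p_orig = p_orig, P_boot = P_boot,
         B = nrow(P_boot), B_requested = nrow(P_boot),
         failures = data.frame(replicate = integer(0), reason = character(0)),
         per_replicate = vector("list", nrow(P_boot)),
         ids = ids %||% as.character(seq_along(p_orig)),
         master_seed = 0L, spec = strategy_logistic(),
         original_fit = NULL),
    class = "predstab_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort with a saturated binary predictor: X = 1 has e1 events / n1 total,
# X = 0 has e0 / n0. Closed-form logistic MLE: slope = log odds ratio,
# intercept = log odds in the X = 0 group.
binary_cohort <- function(e1, n1, e0, n0) {
  df <- data.frame(
    y = c(rep(1, e1), rep(0, n1 - e1), rep(1, e0), rep(0, n0 - e0)),
    x = c(rep(1, n1), rep(0, n0)))
  validate_cohort(df, outcome = "y")
}

# Small well-behaved development cohort for pipeline tests.
quick_cohort <- function(n = 120, seed = 42) {
  generate_simulation_cohort(n, seed = seed)
}
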