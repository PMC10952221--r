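# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible child seeds from one master seed. Pre-drawing the
# whole vector makes replicate b reproducible independently of the order in
# which replicates are executed.
derive_seeds <- function(master_seed, k) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, k))
}

# Probabilities are clipped before any logit transform; tree ensembles emit
# exact 0/1.
RISK_EPS <- 1e-6

clip_risk <- function(p, eps = RISK_EPS) pmin(pmax(p, eps), 1 - eps)

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
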