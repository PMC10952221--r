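#' Generate a synthetic GUSTO-like acute-MI cohort
#'
#' A synthetic stand-in for a 30-day-mortality cohort after acute
#' myocardial infarction, with the classical seven-predictor roster: Sex
#' (1 = female), Age (years), Hypertension, Hypotension, Tachycardia,
#' Previous MI (all 0/1) and ST-elevation lead count (0-11). It is an
#' explicit fixture, not a claim about the real GUSTO-I data: covariate
#' distributions and relative coefficient sizes (including a sex log-odds
#' of log(1.15), females vs males) are fixed and documented below; the
#' intercept and a common coefficient scale are solved numerically so the
#' population has the requested overall risk and c-statistic.
#'
#' Fixture definition (relative log-odds before scaling; age centered at
#' 61): sex ~ Bernoulli(0.25), coef log(1.15); age ~ Normal(61, 11), coef
#' 0.08/year; hypertension ~ Bernoulli(0.38), coef 0.2; hypotension ~
#' Bernoulli(0.08), coef 0.9; tachycardia ~ Bernoulli(0.32), coef 0.6;
#' previous MI ~ Bernoulli(0.17), coef 0.45; ST-elevation leads ~
#' Binomial(11, 0.25), coef 0.09/lead.
#'
#' @param n Number of individuals (>= 100).
#' @param target_prevalence Population mean event risk (default 0.07).
#' @param target_c Population c-statistic of the true risks (default 0.8).
#' @param seed Seed for the cohort's private RNG stream.
#' @return A `predstab_cohort` with predictors `sex`, `age`, `hyp`, `hotn`,
#'   `tach`, `pmi`, `ste`, subgroup labels `female`/`male`, and `true_risk`
#'   attached.
#' @examples
#' co <- generate_gusto_like(752, seed = 9)
#' co$prevalence
#' @export
generate_gusto_like <- function(n, target_prevalence = 0.07, target_c = 0.8,
                                seed = NULL) {
  stopifnot(n >= 100)
  sol <- gusto_calibration(target_prevalence, target_c)
  with_seed(seed, {
    V <- gusto_covariates(n)
    lp <- sol$intercept + sol$scale * gusto_raw_lp(V)
    tr <- plogis(lp)
    y <- rbinom(n, 1L, tr)
    df <- data.frame(y = y, V, true_risk = tr,
                     subgroup = ifelse(V[, "sex"] == 1, "female", "male"),
                     check.names = FALSE)
    validate_cohort(df, outcome = "y", subgroup = "subgroup",
                    true_risk = "true_risk")
  })
}

# Fixture coefficient vector (relative scale) and covariate sampler.
GUSTO_COEFS <- c(sex = log(1.15), age = 0.08, hyp = 0.2, hotn = 0.9,
                 tach = 0.6, pmi = 0.45, ste = 0.09)
GUSTO_AGE_CENTER <- 61

gusto_covariates <- function(n) {
  cbind(sex = rbinom(n, 1L, 0.25),
        age = rnorm(n, GUSTO_AGE_CENTER, 11),
        hyp = rbinom(n, 1L, 0.38),
        hotn = rbinom(n, 1L, 0.08),
        tach = rbinom(n, 1L, 0.32),
        pmi = rbinom(n, 1L, 0.17),
        ste = rbinom(n, 11L, 0.25))
}

gusto_raw_lp <- function(V) {
  Vc <- V
  Vc[, "age"] <- Vc[, "age"] - GUSTO_AGE_CENTER
  as.vector(Vc %*% GUSTO_COEFS)
}

# Solve (intercept, scale) so the population mean risk and c-statistic hit
# their targets, on a fixed internal Monte Carlo sample so the solution is
# a deterministic function of the targets. Cached per target pair.
.gusto_cache <- new.env(parent = emptyenv())

gusto_calibration <- function(prevalence, target_c, m = 200000L) {
  key <- paste(prevalence, target_c, sep = "|")
  if (!is.null(.gusto_cache[[key]])) return(.gusto_cache[[key]])
  if (prevalence <= 0 || prevalence >= 1 || target_c <= 0.5 || target_c >= 1)
    stop("infeasible targets: need prevalence in (0,1) and c in (0.5, 1)",
         call. = FALSE)
  ref <- with_seed(202306L, {
    V <- gusto_covariates(m)
    list(lp = gusto_raw_lp(V), u = runif(m))
  })
  solve_intercept <- function(s) {
    uniroot(function(a) mean(plogis(a + s * ref$lp)) - prevalence,
            lower = -30, upper = 10, tol = 1e-9)$root
  }
  c_at <- function(s) {
    a <- solve_intercept(s)
    p <- plogis(a + s * ref$lp)
    y <- as.integer(ref$u < p)  # common uniforms keep c smooth in s
    c_statistic(p, y)
  }
  lo <- 0.05; hi <- 6
  if (c_at(hi) < target_c || c_at(lo) > target_c)
    stop(sprintf("infeasible (prevalence, c) target pair (%.3g, %.3g)",
                 prevalence, target_c), call. = FALSE)
  s <- uniroot(function(s) c_at(s) - target_c, lower = lo, upper = hi,
               tol = 1e-4)$root
  sol <- list(intercept = solve_intercept(s), scale = s)
  .gusto_cache[[key]] <- sol
  sol
}

#' Load a GUSTO-I CSV export as a cohort
#'
#' Optional convenience loader for a CSV export of the freely available
#' GUSTO-I trial data. The assumed column mapping (configurable) is:
#' outcome `day30` (or `death`), predictors `sex` (0 = male, 1 = female),
#' `age`, `hyp` (hypertension), `hotn` (hypotension), `hrt` (tachycardia),
#' `pmi` (previous MI) and `ste` (number of leads with ST elevation).
#' Nothing in the package requires this loader; the synthetic
#' [generate_gusto_like()] fixture backs all examples and tests.
#'
#' @param path CSV file path (header row required).
#' @param outcome Outcome column name.
#' @param predictors Character vector of the seven predictor column names.
#' @param delim Field delimiter.
#' @return A `predstab_cohort` with `sex` also used as subgroup label.
#' @export
read_gusto_csv <- function(path, outcome = "day30",
                           predictors = c("sex", "age", "hyp", "hotn",
                                          "hrt", "pmi", "ste"),
                           delim = ",") {
  tab <- read.csv(path, sep = delim, check.names = FALSE)
  if (!outcome %in% names(tab) && "death" %in% names(tab)) outcome <- "death"
  missing_cols <- setdiff(c(outcome, predictors), names(tab))
  if (length(missing_cols))
    stop("GUSTO export lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- tab[c(outcome, predictors)]
  # sex may be exported as labels
  if (!is.numeric(tab[[predictors[1L]]]))
    tab[[predictors[1L]]] <-
      as.integer(tolower(as.character(tab[[predictors[1L]]])) %in%
                   c("female", "f", "1"))
  tab$subgroup <- ifelse(tab[[predictors[1L]]] == 1, "female", "male")
  validate_cohort(tab, outcome = outcome, subgroup = "subgroup")
}
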