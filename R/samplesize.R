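#' Minimum sample size to estimate the overall risk precisely
#'
#' The smallest development sample size n such that the observed overall
#' event proportion estimates the true overall risk phi to within an
#' absolute margin delta with (1 - alpha) confidence:
#' n = ceil( z^2 * phi (1 - phi) / delta^2 ), z the standard-normal
#' (1 - alpha/2) quantile. Anticipated prevalence 0.5 with margin 0.05
#' gives n = 385. This targets level-1 stability (the model's mean
#' estimated risk / calibration-in-the-large) only.
#'
#' @param phi Anticipated outcome prevalence, in (0, 1).
#' @param delta Absolute precision margin (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return An object of class `predstab_samplesize` with elements `n`,
#'   `criterion`, `inputs` and `expected_events` (= round(n * phi)).
#' @examples
#' n_for_overall_risk(0.5, 0.05)$n   # 385
#' @export
n_for_overall_risk <- function(phi, delta, alpha = 0.05) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)", call. = FALSE)
  if (delta <= 0) stop("delta must be positive (delta = 0 needs infinite n)",
                       call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  z <- qnorm(1 - alpha / 2)
  n <- ceiling(z^2 * phi * (1 - phi) / delta^2)
  new_samplesize(n, "overall_risk_precision",
                 list(phi = phi, delta = delta, alpha = alpha))
}

#' Minimum sample size targeting a uniform shrinkage factor
#'
#' The smallest n such that the expected heuristic uniform shrinkage factor
#' of a p-parameter logistic model with anticipated Cox-Snell R-squared
#' R2_CS is at least S_target:
#' n = ceil( p / ((S_target - 1) * ln(1 - R2_CS / S_target)) ).
#' Seven parameters with R2_CS = 0.08 targeting S = 0.9 gives n = 752.
#'
#' @param p Number of candidate predictor parameters (>= 1).
#' @param R2_CS Anticipated Cox-Snell R-squared, in (0, 1).
#' @param S_target Target uniform shrinkage factor, in (0, 1); must exceed
#'   `R2_CS`.
#' @param phi Optional anticipated prevalence, used only to report the
#'   expected event count.
#' @return A `predstab_samplesize`.
#' @examples
#' n_for_shrinkage(7, 0.08, 0.9)$n   # 752
#' @export
n_for_shrinkage <- function(p, R2_CS, S_target, phi = NULL) {
  if (p < 1) stop("p must be at least 1", call. = FALSE)
  if (R2_CS <= 0 || R2_CS >= 1) stop("R2_CS must be in (0, 1)", call. = FALSE)
  if (S_target >= 1 || S_target <= 0)
    stop("S_target must be in (0, 1); S_target >= 1 needs infinite n",
         call. = FALSE)
  if (R2_CS >= S_target)
    stop("R2_CS must be smaller than S_target (log undefined otherwise)",
         call. = FALSE)
  n <- ceiling(p / ((S_target - 1) * log(1 - R2_CS / S_target)))
  new_samplesize(n, "uniform_shrinkage",
                 list(p = p, R2_CS = R2_CS, S_target = S_target, phi = phi))
}

new_samplesize <- function(n, criterion, inputs) {
  ev <- if (!is.null(inputs$phi)) round(n * inputs$phi) else NA_integer_
  structure(list(n = as.integer(n), criterion = criterion, inputs = inputs,
                 expected_events = ev),
            class = "predstab_samplesize")
}

#' @export
print.predstab_samplesize <- function(x, ...) {
  cat(sprintf("<predstab_samplesize> criterion: %s\n", x$criterion))
  cat(sprintf("  minimum n = %d participants", x$n))
  if (!is.na(x$expected_events))
    cat(sprintf("  (~%d expected events at prevalence %.3g)",
                x$expected_events, x$inputs$phi))
  cat("\n  inputs:",
      paste(names(x$inputs)[!vapply(x$inputs, is.null, logical(1))],
            unlist(x$inputs), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Events per predictor parameter
#'
#' The number of outcome events divided by the number of candidate
#' predictor parameters — the classical (if crude) yardstick of overfitting
#' risk. Returns the raw ratio; round for display.
#'
#' @param events Number of outcome events (>= 0).
#' @param parameters Number of candidate predictor parameters (>= 1).
#' @return The ratio events/parameters as a double.
#' @examples
#' round(epp(2851, 7))  # 407
#' @export
epp <- function(events, parameters) {
  if (parameters < 1) stop("parameters must be at least 1", call. = FALSE)
  if (events < 0) stop("events must be non-negative", call. = FALSE)
  events / parameters
}
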