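#' Per-individual mean absolute prediction error (MAPE)
#'
#' For individual i, MAPE_i = sum_b |p_bi - p_i| / B: the mean absolute
#' difference between the bootstrap models' predictions and the original
#' model's prediction. Although no true risk is involved, "error" is apt:
#' it is the error the original prediction would carry if a bootstrap model
#' were the truth.
#'
#' @param run A `predstab_run` from [run_stability_bootstrap()].
#' @return Named numeric vector of length N (names = individual ids).
#' @export
mape_per_individual <- function(run) {
  stopifnot(inherits(run, "predstab_run"))
  if (run$B == 0L) stop("no successful bootstrap replicates", call. = FALSE)
  m <- colMeans(abs(sweep(run$P_boot, 2L, run$p_orig)))
  names(m) <- run$ids
  m
}

#' Average MAPE across individuals
#'
#' The double mean sum_b sum_i |p_bi - p_i| / (B N); identically the mean
#' of [mape_per_individual()]. A single-number instability summary, always
#' to be read alongside the per-individual MAPE distribution.
#'
#' @inheritParams mape_per_individual
#' @return A scalar.
#' @export
average_mape <- function(run) {
  mean(mape_per_individual(run))
}

#' Per-individual stability intervals and smoothed bounds
#'
#' For each individual, the central `level` range (default the 2.5th and
#' 97.5th percentiles) of their B bootstrap-model predictions. The lower
#' and upper bounds are additionally smoothed across individuals against
#' the original prediction with a LOESS curve, forming a 95% stability
#' interval band for the whole risk range. These are stability intervals,
#' not confidence intervals: they describe variability of the model-building
#' process, not uncertainty about a true parameter.
#'
#' Percentiles use linear interpolation between order statistics (R
#' `quantile` type 7).
#'
#' @inheritParams mape_per_individual
#' @param level Central coverage of the interval, in (0, 1).
#' @param span LOESS span for smoothing the bounds across individuals;
#'   values between 0.2 and 0.8 are generally sensible.
#' @return An object of class `predstab_intervals`: data.frame `individual`
#'   with columns `id`, `p_orig`, `lower`, `upper`, `lower_smooth`,
#'   `upper_smooth`, plus `smooth_fun`, a list of two functions evaluating
#'   the smoothed lower/upper bounds at arbitrary original-risk values
#'   (clipped to \[0, 1\], ordering enforced).
#' @export
stability_intervals <- function(run, level = 0.95, span = 0.5) {
  stopifnot(inherits(run, "predstab_run"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (run$B < 40 && level >= 0.95)
    warning("fewer than 40 replicates: extreme percentiles are unreliable",
            call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- apply(run$P_boot, 2L, quantile, probs = c(alpha, 1 - alpha),
              type = 7, names = FALSE)
  df <- data.frame(id = run$ids, p_orig = run$p_orig,
                   lower = qs[1L, ], upper = qs[2L, ])

  # LOESS needs enough distinct x values; fall back to linear interpolation
  # of the raw bounds for tiny or degenerate runs
  interp_fallback <- function(col) {
    o <- order(df$p_orig)
    if (length(unique(df$p_orig)) < 2L)
      return(function(p) rep(mean(df[[col]]), length(p)))
    function(p) stats::approx(df$p_orig[o], df[[col]][o], xout = p,
                              rule = 2, ties = mean)$y
  }
  lo_fit <- tryCatch(suppressWarnings(
    loess(lower ~ p_orig, data = df, span = span, degree = 1)),
    error = function(e) NULL)
  up_fit <- tryCatch(suppressWarnings(
    loess(upper ~ p_orig, data = df, span = span, degree = 1)),
    error = function(e) NULL)
  lo_fallback <- interp_fallback("lower")
  up_fallback <- interp_fallback("upper")
  eval_bounds <- function(p) {
    lo <- if (is.null(lo_fit)) lo_fallback(p) else
      predict(lo_fit, newdata = data.frame(p_orig = p))
    up <- if (is.null(up_fit)) up_fallback(p) else
      predict(up_fit, newdata = data.frame(p_orig = p))
    lo[is.na(lo)] <- lo_fallback(p)[is.na(lo)]
    up[is.na(up)] <- up_fallback(p)[is.na(up)]
    lo <- pmin(pmax(lo, 0), 1)
    up <- pmin(pmax(up, 0), 1)
    cbind(lower = pmin(lo, up), upper = pmax(lo, up))
  }
  sm <- eval_bounds(df$p_orig)
  df$lower_smooth <- sm[, "lower"]
  df$upper_smooth <- sm[, "upper"]
  structure(list(
    individual = df,
    level = level, span = span,
    smooth_fun = list(
      lower = function(p) eval_bounds(p)[, "lower"],
      upper = function(p) eval_bounds(p)[, "upper"])),
    class = "predstab_intervals")
}

#' @export
print.predstab_intervals <- function(x, ...) {
  cat(sprintf("<predstab_intervals> %.0f%% stability intervals for %d individuals (span %.2f)\n",
              100 * x$level, nrow(x$individual), x$span))
  print(head(x$individual, 5L))
  invisible(x)
}

#' Classification instability index
#'
#' The proportion of bootstrap models classifying an individual on the
#' opposite side of the risk threshold from the original model — an
#' estimate of the probability that a different example model would have
#' produced a different classification. A risk equal to the threshold
#' counts as "positive" (risk >= threshold).
#'
#' @inheritParams mape_per_individual
#' @param threshold Classification threshold in (0, 1).
#' @return Named numeric vector in \[0, 1\], one entry per individual.
#' @export
classification_instability_index <- function(run, threshold) {
  stopifnot(inherits(run, "predstab_run"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  orig_class <- run$p_orig >= threshold
  boot_class <- run$P_boot >= threshold
  idx <- colMeans(boot_class != rep(orig_class, each = nrow(boot_class)))
  names(idx) <- run$ids
  idx
}

#' Concordance statistic (c-statistic / AUC)
#'
#' The probability that a randomly chosen event receives a higher risk than
#' a randomly chosen non-event, with ties counting one half. Computed from
#' mid-ranks, which is exactly the all-pairs definition.
#'
#' @param risks Numeric vector of estimated risks (any monotone score works;
#'   c is invariant to strictly increasing transforms).
#' @param y 0/1 outcome vector with at least one event and one non-event.
#' @return A scalar in \[0, 1\].
#' @export
c_statistic <- function(risks, y) {
  if (length(risks) != length(y)) stop("length mismatch", call. = FALSE)
  if (!is_binary01(y)) stop("y must be 0/1", call. = FALSE)
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0)
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  r <- rank(risks)  # mid-ranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap distribution of the c-statistic
#'
#' Applies [c_statistic()] to each bootstrap model's predictions on the
#' original dataset. The wider the spread, the greater the instability in
#' the model's discrimination performance.
#'
#' @inheritParams mape_per_individual
#' @param y 0/1 outcome vector of the original cohort.
#' @return Numeric vector of length B, with a `summary` attribute holding
#'   min, 2.5th/97.5th percentiles, median and max.
#' @export
bootstrap_c_distribution <- function(run, y) {
  stopifnot(inherits(run, "predstab_run"))
  cs <- apply(run$P_boot, 1L, c_statistic, y = y)
  attr(cs, "summary") <- c(
    min = min(cs),
    p2.5 = unname(quantile(cs, 0.025, type = 7)),
    median = median(cs),
    p97.5 = unname(quantile(cs, 0.975, type = 7)),
    max = max(cs))
  cs
}

#' Flexible calibration curve
#'
#' Smoothed observed event probability as a function of estimated risk,
#' for comparison with the 45-degree line of perfect calibration. The
#' default smoother is local regression of the 0/1 outcome on the risk
#' scale; `method = "spline"` uses a penalized logistic spline on the logit
#' scale (requires mgcv). The evaluation grid is restricted to the 1st-99th
#' percentiles of the risks to avoid edge extrapolation.
#'
#' @param risks Estimated risks in \[0, 1\].
#' @param y 0/1 outcomes.
#' @param method `"loess"` (default) or `"spline"`.
#' @param span LOESS span.
#' @param grid Optional explicit grid of risk values; defaults to 50 points
#'   spanning the 1st-99th percentile of `risks`.
#' @return An object of class `predstab_calibration`: data.frame with
#'   columns `grid` and `observed`, attributes `method` and `degenerate`.
#'   Constant risks yield the degenerate single point (risk, mean(y)).
#' @export
calibration_curve <- function(risks, y, method = c("loess", "spline"),
                              span = 0.75, grid = NULL) {
  method <- match.arg(method)
  if (length(risks) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 20)
    warning("fewer than 20 observations: calibration curve is unreliable",
            call. = FALSE)
  if (diff(range(risks)) < 1e-12) {
    out <- data.frame(grid = risks[1L], observed = mean(y))
    return(structure(out, method = method, degenerate = TRUE,
                     class = c("predstab_calibration", "data.frame")))
  }
  if (is.null(grid)) {
    qr <- quantile(risks, c(0.01, 0.99), type = 7, names = FALSE)
    grid <- seq(qr[1L], qr[2L], length.out = 50L)
  }
  obs <- switch(method,
    loess = {
      fit <- loess(y ~ risks, span = span, degree = 2,
                   control = loess.control(surface = "interpolate",
                                           statistics = "none"))
      predict(fit, newdata = data.frame(risks = grid))
    },
    spline = {
      if (!requireNamespace("mgcv", quietly = TRUE))
        stop("method = 'spline' requires the mgcv package", call. = FALSE)
      lp <- qlogis(clip_risk(risks))
      fit <- mgcv::gam(y ~ s(lp), family = binomial())
      as.vector(predict(fit, newdata = data.frame(lp = qlogis(clip_risk(grid))),
                        type = "response"))
    })
  keep <- !is.na(obs)
  out <- data.frame(grid = grid[keep], observed = pmin(pmax(obs[keep], 0), 1))
  structure(out, method = method, degenerate = FALSE,
            class = c("predstab_calibration", "data.frame"))
}

#' Decision curve (net benefit across risk thresholds)
#'
#' Net benefit of treating at-or-above a threshold p_t:
#' NB(p_t) = TP/N - (FP/N) * p_t / (1 - p_t), where a positive
#' classification is risk >= p_t. Reference strategies: treat-all,
#' NB = phi - (1 - phi) p_t / (1 - p_t) with phi the event prevalence, and
#' treat-none, NB = 0. `nb_min`, the minimum of the model's net benefit and
#' its advantage over treat-all, is a compact display when overlaying many
#' bootstrap curves.
#'
#' @param risks Estimated risks in \[0, 1\].
#' @param y 0/1 outcomes.
#' @param thresholds Vector of thresholds, all in (0, 1). Default grid
#'   0.01-0.50 by 0.01.
#' @return An object of class `predstab_decision_curve`: data.frame with
#'   columns `threshold`, `nb_model`, `nb_treat_all`, `nb_treat_none`,
#'   `nb_min`.
#' @export
net_benefit_curve <- function(risks, y, thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (length(risks) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("all thresholds must lie strictly inside (0, 1)", call. = FALSE)
  n <- length(y)
  phi <- mean(y)
  nb_model <- vapply(thresholds, function(pt) {
    pos <- risks >= pt
    tp <- sum(pos & y == 1) / n
    fp <- sum(pos & y == 0) / n
    tp - fp * pt / (1 - pt)
  }, numeric(1))
  nb_all <- phi - (1 - phi) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds,
                    nb_model = nb_model,
                    nb_treat_all = nb_all,
                    nb_treat_none = 0,
                    nb_min = pmin(nb_model, nb_model - nb_all))
  structure(out, prevalence = phi,
            class = c("predstab_decision_curve", "data.frame"))
}

#' Subgroup (fairness) stability reports
#'
#' Recomputes all instability metrics restricting the individuals to each
#' subgroup. Bootstrap refits are NOT redone: the same B bootstrap models
#' are used and their prediction columns sliced, so differences between
#' subgroup reports reflect genuine differences in prediction stability,
#' not resampling noise.
#'
#' @inheritParams mape_per_individual
#' @param y 0/1 outcomes of the original cohort.
#' @param labels Vector of subgroup labels, one per individual. Labels with
#'   fewer than 2 members are excluded with a warning.
#' @param ... Passed to [stability_report()] for each subgroup.
#' @return Named list mapping label to `predstab_report`.
#' @export
subgroup_stability <- function(run, y, labels, ...) {
  stopifnot(inherits(run, "predstab_run"))
  labels <- factor(as.character(labels))
  if (length(labels) != length(run$p_orig))
    stop("labels must have one entry per individual", call. = FALSE)
  out <- list()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < 2L) {
      warning(sprintf("subgroup '%s' has < 2 members; excluded", lv),
              call. = FALSE)
      next
    }
    out[[lv]] <- stability_report(run_subset_individuals(run, idx), y[idx],
                                  subgroups = NULL, ...)
  }
  out
}
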