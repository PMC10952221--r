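#' Model-building strategies
#'
#' A strategy is a self-contained recipe that can be refit from scratch on
#' any resample of the development data and return event risks in \[0, 1\]
#' for any row. Everything data-driven in the recipe — penalty tuning by
#' cross-validation, hyperparameter search, random development/recalibration
#' splits — is part of the strategy and is re-executed in every bootstrap
#' refit, because instability is a property of the whole model-building
#' process, not just of the final coefficient estimates.
#'
#' Two fits with identical strategy, data and seed produce identical
#' predictions.
#'
#' @param cv_folds Number of cross-validation folds for penalty selection.
#' @param lambda Optional fixed LASSO penalty, bypassing cross-validation.
#'   `Inf` gives the fully shrunken intercept-only model (all predictions
#'   equal the resample prevalence).
#' @param stratified_cv If `TRUE`, CV folds are allocated separately within
#'   events and non-events. Defaults to `FALSE` (plain random folds, the
#'   standard implementation); stratification is applied automatically as a
#'   fallback when plain CV fails on a degenerate fold.
#' @param n_trees,max_depth,min_leaf Random-forest size, depth limit
#'   (`NULL` = unlimited) and minimum terminal-node size.
#' @param auto_tune If `TRUE`, `max_depth` and `min_leaf` are chosen by
#'   seeded 5-fold cross-validated log-loss over `tune_grid` at every
#'   (re)fit — deliberately so, since data-driven tuning is itself a source
#'   of instability.
#' @param tune_grid Data frame of candidate `max_depth` (`NA` = unlimited)
#'   and `min_leaf` values searched when `auto_tune = TRUE`.
#' @param base A strategy object for the model fit on the development part
#'   of the split.
#' @param dev_n,recal_n Sizes of the random development / recalibration
#'   partition (must sum to N at fit time).
#'
#' @return An object of class `predstab_strategy` describing the recipe;
#'   pass it to [fit_strategy()] or [run_stability_bootstrap()].
#' @seealso [fit_strategy()], [predict_risk()], [run_stability_bootstrap()]
#' @name strategies
NULL

new_strategy <- function(kind, ...) {
  structure(list(kind = kind, ...),
            class = c(paste0("predstab_strategy_", kind), "predstab_strategy"))
}

#' @rdname strategies
#' @export
strategy_logistic <- function() {
  new_strategy("unpenalized_logistic")
}

#' @rdname strategies
#' @export
strategy_lasso <- function(cv_folds = 10, lambda = NULL,
                           stratified_cv = FALSE) {
  stopifnot(cv_folds >= 2)
  new_strategy("lasso_logistic", cv_folds = as.integer(cv_folds),
               lambda = lambda, stratified_cv = isTRUE(stratified_cv))
}

#' @rdname strategies
#' @export
strategy_uniform_shrinkage <- function() {
  new_strategy("uniform_shrinkage_logistic")
}

#' @rdname strategies
#' @export
strategy_random_forest <- function(n_trees = 100, max_depth = NULL,
                                   min_leaf = 1, auto_tune = FALSE,
                                   tune_grid = default_forest_grid()) {
  new_strategy("random_forest", n_trees = as.integer(n_trees),
               max_depth = max_depth, min_leaf = as.integer(min_leaf),
               auto_tune = isTRUE(auto_tune), tune_grid = tune_grid)
}

#' @rdname strategies
#' @export
strategy_split_recalibrated <- function(base, dev_n, recal_n) {
  stopifnot(inherits(base, "predstab_strategy"), dev_n >= 2, recal_n >= 2)
  new_strategy("split_recalibrated", base = base,
               dev_n = as.integer(dev_n), recal_n = as.integer(recal_n))
}

#' @export
print.predstab_strategy <- function(x, ...) {
  cat(sprintf("<predstab_strategy: %s>\n", x$kind))
  hp <- x[setdiff(names(x), c("kind", "base", "tune_grid"))]
  if (length(hp))
    cat(" ", paste(names(hp), vapply(hp, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = " = ", collapse = "; "), "\n")
  if (!is.null(x$base)) { cat("  base: "); print(x$base) }
  invisible(x)
}

#' Default hyperparameter grid for auto-tuned random forests
#'
#' Searched by 5-fold cross-validated log-loss: tree depth 2, 3, 5 or
#' unlimited (`NA`) crossed with minimum leaf size 1, 5 or 10.
#' @return A data frame with columns `max_depth` and `min_leaf`.
#' @export
default_forest_grid <- function() {
  expand.grid(max_depth = c(2, 3, 5, NA), min_leaf = c(1, 5, 10))
}

#' Fit a model-building strategy on a cohort
#'
#' Executes the full recipe described by `spec` on `cohort`, using `seed`
#' for every internal source of randomness (fold allocation, forest
#' bootstrap, random splits). The returned fit predicts deterministically.
#'
#' @param spec A strategy from [strategy_logistic()] and friends.
#' @param cohort A [validate_cohort()] cohort (or any list with numeric
#'   matrix `X` and 0/1 vector `y`).
#' @param seed Integer seed for the refit's private RNG stream.
#' @return A `predstab_fit` with elements `spec`, `seed` and `diagnostics`
#'   (selected penalty, shrinkage factor, tuned hyperparameters,
#'   recalibration slope/intercept, as applicable).
#' @examples
#' co <- generate_simulation_cohort(200, seed = 1)
#' fit <- fit_strategy(strategy_logistic(), co, seed = 1)
#' head(predict_risk(fit, co))
#' @export
fit_strategy <- function(spec, cohort, seed = NULL) {
  UseMethod("fit_strategy")
}

#' @export
fit_strategy.default <- function(spec, cohort, seed = NULL) {
  stop("not a predstab strategy object", call. = FALSE)
}

#' Predict event risks from a fitted strategy
#'
#' @param fit A fit from [fit_strategy()].
#' @param newdata A cohort, numeric matrix or data.frame containing the
#'   predictor columns the strategy was fit on.
#' @param ... Unused.
#' @return Numeric vector of risks in \[0, 1\], one per row.
#' @export
predict_risk <- function(fit, newdata, ...) UseMethod("predict_risk")

new_fit <- function(kind, spec, seed, diagnostics, ...) {
  structure(list(spec = spec, seed = seed, diagnostics = diagnostics, ...),
            class = c(paste0("predstab_fit_", kind), "predstab_fit"))
}

#' @export
print.predstab_fit <- function(x, ...) {
  cat(sprintf("<predstab_fit: %s>\n", x$spec$kind))
  d <- x$diagnostics
  if (length(d)) {
    flat <- vapply(d, function(v) paste(format(v, digits = 4), collapse = ","),
                   character(1))
    cat(" ", paste(names(flat), flat, sep = " = ", collapse = "; "), "\n")
  }
  invisible(x)
}

predictor_matrix <- function(newdata, cols) {
  X <- if (inherits(newdata, "predstab_cohort")) newdata$X
       else as.matrix(as.data.frame(newdata))
  missing_cols <- setdiff(cols, colnames(X))
  if (length(missing_cols))
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- X[, cols, drop = FALSE]
  storage.mode(X) <- "double"
  X
}

## ---- unpenalized logistic -------------------------------------------------

# Maximum-likelihood logistic fit on a raw matrix. Collinear or constant
# columns are dropped (coefficient pinned at 0); perfect separation and
# non-convergence raise rather than returning a silently unstable fit.
logistic_mle <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    glm.fit(Xd, y, family = binomial(), control = list(maxit = 100)))
  if (fit$deviance < 1e-7)
    stop("perfect separation: maximum-likelihood logistic fit does not exist",
         call. = FALSE)
  if (!fit$converged)
    stop("logistic fit did not converge", call. = FALSE)
  cf <- coef(fit)
  dropped <- names(cf)[-1][is.na(cf[-1])]
  cf[is.na(cf)] <- 0
  null_dev <- binom_deviance(rep(mean(y), length(y)), y)
  list(intercept = cf[1L], beta = cf[-1L],
       deviance = fit$deviance, null_deviance = null_dev,
       dropped = dropped)
}

binom_deviance <- function(p, y) {
  p <- clip_risk(p)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @export
fit_strategy.predstab_strategy_unpenalized_logistic <- function(spec, cohort,
                                                                seed = NULL) {
  m <- logistic_mle(cohort$X, cohort$y)
  new_fit("glm_linear", spec, seed,
          diagnostics = list(deviance = m$deviance,
                             lr_chi2 = m$null_deviance - m$deviance,
                             dropped = m$dropped),
          intercept = m$intercept, beta = m$beta,
          columns = colnames(cohort$X))
}

#' @export
predict_risk.predstab_fit_glm_linear <- function(fit, newdata, ...) {
  X <- predictor_matrix(newdata, fit$columns)
  as.vector(plogis(fit$intercept + X %*% fit$beta))
}

## ---- LASSO logistic -------------------------------------------------------

strat_fold_ids <- function(y, k) {
  f <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

#' @export
fit_strategy.predstab_strategy_lasso_logistic <- function(spec, cohort,
                                                          seed = NULL) {
  y <- cohort$y
  X <- cohort$X
  if (!is.null(spec$lambda) && is.infinite(spec$lambda)) {
    # fully shrunken: intercept-only, predictions = prevalence (kept exact,
    # including degenerate resamples with prevalence 0 or 1)
    return(new_fit("const", spec, seed,
                   diagnostics = list(lambda = Inf),
                   const_risk = mean(y), columns = colnames(X)))
  }
  if (sum(y) == 0L || sum(y) == length(y))
    stop("degenerate outcome: resample has no events or no non-events",
         call. = FALSE)
  # glmnet needs >= 2 columns; pad single-predictor designs with a zero dummy
  padded <- ncol(X) < 2L
  if (padded) X <- cbind(X, `.pad0` = 0)

  with_seed(seed, {
    if (!is.null(spec$lambda)) {
      gfit <- glmnet::glmnet(X, y, family = "binomial", nlambda = 30,
                             lambda.min.ratio = 1e-4)
      cf <- as.vector(coef(gfit, s = spec$lambda, exact = FALSE))
      lambda_sel <- spec$lambda
    } else {
      n <- length(y)
      k <- min(spec$cv_folds, n %/% 2L)
      fit_cv <- function(foldid)
        glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                          lambda.min.ratio = 1e-4, nlambda = 100)
      cv <- tryCatch(
        suppressWarnings(fit_cv(sample(rep_len(seq_len(k), n)))),
        error = function(e) e)
      if (spec$stratified_cv || inherits(cv, "error"))
        cv <- tryCatch(suppressWarnings(fit_cv(strat_fold_ids(y, k))),
                       error = function(e) e)
      if (inherits(cv, "error"))
        stop("cross-validated penalty selection failed: ",
             conditionMessage(cv), call. = FALSE)
      cf <- as.vector(coef(cv, s = "lambda.min"))
      lambda_sel <- cv$lambda.min
    }
    beta <- cf[-1L]
    names(beta) <- colnames(X)
    if (padded) beta <- beta[names(beta) != ".pad0"]
    new_fit("glm_linear", spec, seed,
            diagnostics = list(lambda = lambda_sel,
                               excluded = names(beta)[beta == 0]),
            intercept = cf[1L], beta = beta,
            columns = names(beta))
  })
}

#' @export
predict_risk.predstab_fit_const <- function(fit, newdata, ...) {
  n <- if (inherits(newdata, "predstab_cohort")) newdata$n
       else nrow(as.matrix(newdata))
  rep(fit$const_risk, n)
}

## ---- uniform heuristic shrinkage ------------------------------------------

#' @export
fit_strategy.predstab_strategy_uniform_shrinkage_logistic <- function(
    spec, cohort, seed = NULL) {
  m <- logistic_mle(cohort$X, cohort$y)
  chi2 <- m$null_deviance - m$deviance
  p_eff <- length(m$beta) - length(m$dropped)
  if (p_eff < 1L)
    stop("shrinkage degenerate: no estimable predictor parameters",
         call. = FALSE)
  if (chi2 <= p_eff)
    stop(sprintf(
      "shrinkage degenerate: model chi-squared (%.3f) does not exceed the number of predictor parameters (%d)",
      chi2, p_eff), call. = FALSE)
  S <- (chi2 - p_eff) / chi2
  beta_s <- S * m$beta
  # re-estimate the intercept against the shrunken linear predictor as an
  # offset, restoring calibration-in-the-large (mean risk = prevalence)
  off <- as.vector(cohort$X %*% beta_s)
  ifit <- suppressWarnings(
    glm(cohort$y ~ 1, offset = off, family = binomial()))
  a <- coef(ifit)[[1L]]
  new_fit("glm_linear", spec, seed,
          diagnostics = list(S = S, chi2_model = chi2, p = p_eff,
                             new_intercept = a, dropped = m$dropped),
          intercept = a, beta = beta_s,
          columns = colnames(cohort$X))
}

## ---- random forest --------------------------------------------------------

fit_forest_raw <- function(X, y, n_trees, max_depth, min_leaf, seed) {
  ranger::ranger(
    x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
    probability = TRUE, num.trees = n_trees,
    max.depth = if (is.null(max_depth) || is.na(max_depth)) 0 else max_depth,
    min.node.size = min_leaf,
    seed = seed %||% sample.int(.Machine$integer.max - 1L, 1L),
    num.threads = 1, verbose = FALSE)
}

forest_risk <- function(forest, X) {
  pr <- predict(forest, data = as.data.frame(X),
                num.threads = 1, verbose = FALSE)$predictions
  as.vector(pr[, "1"])
}

#' @export
fit_strategy.predstab_strategy_random_forest <- function(spec, cohort,
                                                         seed = NULL) {
  X <- cohort$X
  y <- cohort$y
  with_seed(seed, {
    depth <- spec$max_depth
    leaf <- spec$min_leaf
    tuned <- NULL
    if (spec$auto_tune) {
      sel <- tune_forest(X, y, spec$n_trees, spec$tune_grid)
      depth <- sel$max_depth
      leaf <- sel$min_leaf
      tuned <- sel
    }
    forest <- fit_forest_raw(X, y, spec$n_trees, depth, leaf,
                             seed = sample.int(.Machine$integer.max - 1L, 1L))
    new_fit("forest", spec, seed,
            diagnostics = list(max_depth = depth %||% NA, min_leaf = leaf,
                               tuned = !is.null(tuned)),
            forest = forest, columns = colnames(X))
  })
}

# 5-fold CV log-loss over the candidate grid; folds stratified by outcome so
# every training fold sees both classes. Ties resolved by grid order.
tune_forest <- function(X, y, n_trees, grid, k = 5L) {
  k <- max(2L, min(k, sum(y == 1L), sum(y == 0L)))
  foldid <- strat_fold_ids(y, k)
  loss <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ll <- 0
    for (f in seq_len(k)) {
      tr <- foldid != f
      forest <- fit_forest_raw(X[tr, , drop = FALSE], y[tr], n_trees,
                               grid$max_depth[g], grid$min_leaf[g],
                               seed = sample.int(.Machine$integer.max - 1L, 1L))
      p <- clip_risk(forest_risk(forest, X[!tr, , drop = FALSE]))
      ll <- ll - sum(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
    }
    loss[g] <- ll
  }
  sel <- which.min(loss)
  list(max_depth = if (is.na(grid$max_depth[sel])) NULL else grid$max_depth[sel],
       min_leaf = grid$min_leaf[sel], cv_logloss = loss[sel])
}

#' @export
predict_risk.predstab_fit_forest <- function(fit, newdata, ...) {
  X <- predictor_matrix(newdata, fit$columns)
  forest_risk(fit$forest, X)
}

## ---- split-sample Platt recalibration -------------------------------------

#' @export
fit_strategy.predstab_strategy_split_recalibrated <- function(spec, cohort,
                                                              seed = NULL) {
  n <- cohort$n
  if (spec$dev_n + spec$recal_n != n)
    stop(sprintf("dev_n + recal_n (%d) must equal N (%d)",
                 spec$dev_n + spec$recal_n, n), call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(n)
    dev_idx <- perm[seq_len(spec$dev_n)]
    rec_idx <- perm[spec$dev_n + seq_len(spec$recal_n)]
    y_rec <- cohort$y[rec_idx]
    if (sum(y_rec) == 0L || sum(y_rec) == length(y_rec))
      stop("recalibration part degenerate: no events or no non-events",
           call. = FALSE)
    base_fit <- fit_strategy(spec$base, cohort_subset(cohort, dev_idx),
                             seed = sample.int(.Machine$integer.max - 1L, 1L))
    lp <- qlogis(clip_risk(predict_risk(base_fit,
                                        cohort_subset(cohort, rec_idx))))
    if (sd(lp) < 1e-10) {
      # uninformative base model: recalibration collapses to the holdout
      # prevalence
      a <- qlogis(clip_risk(mean(y_rec)))
      b <- 0
    } else {
      rfit <- suppressWarnings(glm(y_rec ~ lp, family = binomial()))
      a <- coef(rfit)[[1L]]
      b <- coef(rfit)[[2L]]
    }
    new_fit("recalibrated", spec, seed,
            diagnostics = list(recal_intercept = a, recal_slope = b,
                               dev_n = spec$dev_n, recal_n = spec$recal_n),
            base_fit = base_fit, recal_intercept = a, recal_slope = b,
            dev_idx = sort(dev_idx), recal_idx = sort(rec_idx))
  })
}

#' @export
predict_risk.predstab_fit_recalibrated <- function(fit, newdata, ...) {
  lp <- qlogis(clip_risk(predict_risk(fit$base_fit, newdata)))
  as.vector(plogis(fit$recal_intercept + fit$recal_slope * lp))
}

## ---- serialization --------------------------------------------------------

#' Serialize / deserialize a strategy specification
#'
#' Strategies round-trip through a plain JSON block so a report can carry
#' the exact recipe it assessed and the command-line interface can read one
#' from a config file.
#'
#' @param spec A `predstab_strategy`.
#' @param json A JSON string produced by `strategy_to_json()`.
#' @return `strategy_to_json()`: a JSON string; `strategy_from_json()`: a
#'   `predstab_strategy`.
#' @export
strategy_to_json <- function(spec) {
  stopifnot(inherits(spec, "predstab_strategy"))
  as.character(jsonlite::toJSON(strategy_to_list(spec), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

strategy_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$base)) out$base <- strategy_to_list(out$base)
  if (!is.null(out$tune_grid)) out$tune_grid <- as.data.frame(out$tune_grid)
  out
}

#' @rdname strategy_to_json
#' @export
strategy_from_json <- function(json) {
  strategy_from_list(jsonlite::fromJSON(json))
}

strategy_from_list <- function(x) {
  kind <- x$kind
  switch(kind,
    unpenalized_logistic = strategy_logistic(),
    lasso_logistic = strategy_lasso(
      cv_folds = x$cv_folds %||% 10,
      lambda = if (is.null(x$lambda)) NULL else
        (if (identical(x$lambda, "Inf")) Inf else as.numeric(x$lambda)),
      stratified_cv = x$stratified_cv %||% FALSE),
    uniform_shrinkage_logistic = strategy_uniform_shrinkage(),
    random_forest = strategy_random_forest(
      n_trees = x$n_trees %||% 100, max_depth = x$max_depth,
      min_leaf = x$min_leaf %||% 1, auto_tune = x$auto_tune %||% FALSE,
      tune_grid = if (is.null(x$tune_grid)) default_forest_grid()
                  else as.data.frame(x$tune_grid)),
    split_recalibrated = strategy_split_recalibrated(
      base = strategy_from_list(x$base),
      dev_n = x$dev_n, recal_n = x$recal_n),
    stop("unknown strategy kind: ", kind, call. = FALSE))
}

#' Plain-text coefficient table for a linear-predictor fit
#'
#' @param fit A `predstab_fit` from a logistic-family strategy.
#' @return A data.frame with columns `term` and `estimate`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "predstab_fit"))
  if (!is.null(fit$beta))
    data.frame(term = c("(Intercept)", names(fit$beta)),
               estimate = c(fit$intercept, unname(fit$beta)))
  else if (!is.null(fit$const_risk))
    data.frame(term = "(Intercept)",
               estimate = qlogis(clip_risk(fit$const_risk)))
  else
    stop("no coefficient representation for this fit kind", call. = FALSE)
}
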