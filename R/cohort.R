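#' Assemble and validate a development cohort
#'
#' A cohort is the unit of resampling for the stability bootstrap: an N x P
#' numeric predictor matrix, a binary outcome vector (1 = event), optional
#' subgroup labels (for fairness stratification) and optional true risks
#' (simulation studies only, where the data-generating model is known).
#'
#' Missing values are rejected, not imputed: imputation inside every
#' bootstrap refit is rarely practical, and silently completing the data
#' would mask part of the very instability the bootstrap is meant to expose.
#'
#' @param table A data.frame (or object coercible to one) with one row per
#'   participant. All columns other than `outcome`, `subgroup`, `id` and
#'   `true_risk` are taken as numeric predictors.
#' @param outcome Name of the binary outcome column (values 0/1, 1 = event).
#' @param subgroup Optional name of a categorical subgroup label column.
#' @param id Optional name of an identifier column; defaults to row numbers.
#' @param true_risk Optional name of a column of true event probabilities
#'   (only meaningful for simulated data).
#'
#' @return An object of class `predstab_cohort`: a list with elements `X`
#'   (numeric matrix), `y` (0/1 integer vector), `ids` (character),
#'   `subgroup` (factor or NULL), `true_risk` (numeric or NULL).
#'
#' @examples
#' d <- data.frame(y = c(1, 0, 1, 0), age = c(60, 55, 70, 48),
#'                 sex = c(1, 0, 0, 1))
#' co <- validate_cohort(d, outcome = "y")
#' co$n_events  # 2
#' @export
validate_cohort <- function(table, outcome, subgroup = NULL, id = NULL,
                            true_risk = NULL) {
  if (inherits(table, "predstab_cohort")) return(table)  # idempotent
  table <- as.data.frame(table)
  if (nrow(table) < 2L) stop("cohort must have at least 2 rows", call. = FALSE)
  if (!outcome %in% names(table))
    stop(sprintf("outcome column '%s' not found", outcome), call. = FALSE)
  for (col in c(subgroup, id, true_risk)) {
    if (!is.null(col) && !col %in% names(table))
      stop(sprintf("column '%s' not found", col), call. = FALSE)
  }

  special <- c(outcome, subgroup, id, true_risk)
  pred_cols <- setdiff(names(table), special)
  if (length(pred_cols) < 1L)
    stop("cohort must contain at least one predictor column", call. = FALSE)

  check_cols <- c(outcome, pred_cols, true_risk)
  miss <- vapply(table[check_cols], function(x) any(is.na(x)), logical(1))
  if (any(miss)) {
    bad_cols <- names(miss)[miss]
    bad_rows <- which(!complete.cases(table[check_cols]))
    stop(sprintf(
      "missing values are not supported (handle them before assembly): %d row(s) [%s%s] in column(s) %s",
      length(bad_rows),
      paste(head(bad_rows, 10L), collapse = ", "),
      if (length(bad_rows) > 10L) ", ..." else "",
      paste(bad_cols, collapse = ", ")), call. = FALSE)
  }

  y <- table[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!is_binary01(y))
    stop("outcome must contain only 0/1 values (1 = event)", call. = FALSE)
  y <- as.integer(y)
  if (sum(y) == 0L || sum(y) == length(y))
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)

  X <- as.matrix(table[pred_cols])
  if (!is.numeric(X))
    stop("all predictor columns must be numeric", call. = FALSE)
  storage.mode(X) <- "double"

  tr <- NULL
  if (!is.null(true_risk)) {
    tr <- as.numeric(table[[true_risk]])
    if (any(tr < 0 | tr > 1))
      stop("true_risk values must lie in [0, 1]", call. = FALSE)
  }

  ids <- if (is.null(id)) as.character(seq_len(nrow(table)))
         else as.character(table[[id]])
  sg <- if (is.null(subgroup)) NULL else factor(as.character(table[[subgroup]]))

  structure(
    list(X = X, y = y, ids = ids, subgroup = sg, true_risk = tr,
         n = nrow(X), p = ncol(X),
         n_events = sum(y), prevalence = mean(y)),
    class = "predstab_cohort")
}

#' Read a development cohort from a delimited text file
#'
#' @param path Path to a delimited file with a header row.
#' @param delim Field delimiter (default comma).
#' @inheritParams validate_cohort
#' @return A [validate_cohort()] object.
#' @export
read_cohort_csv <- function(path, outcome, subgroup = NULL, id = NULL,
                            true_risk = NULL, delim = ",") {
  tab <- read.csv(path, sep = delim, check.names = FALSE)
  validate_cohort(tab, outcome = outcome, subgroup = subgroup, id = id,
                  true_risk = true_risk)
}

#' Write a cohort back to CSV
#'
#' The written file round-trips through [read_cohort_csv()] to an identical
#' cohort (same predictors, outcome and subgroup labels).
#'
#' @param cohort A `predstab_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "predstab_cohort"))
  out <- data.frame(id = cohort$ids, y = cohort$y, check.names = FALSE)
  out <- cbind(out, as.data.frame(cohort$X))
  if (!is.null(cohort$subgroup)) out$subgroup <- as.character(cohort$subgroup)
  if (!is.null(cohort$true_risk)) out$true_risk <- cohort$true_risk
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.predstab_cohort <- function(x, ...) {
  cat(sprintf("<predstab_cohort>  N = %d, predictors = %d\n", x$n, x$p))
  cat(sprintf("  events: %d  (prevalence %.4f)\n", x$n_events, x$prevalence))
  cat(sprintf("  predictors: %s\n",
              paste(head(colnames(x$X), 8L), collapse = ", ")))
  if (!is.null(x$subgroup))
    cat(sprintf("  subgroups: %s\n",
                paste(levels(x$subgroup), collapse = ", ")))
  if (!is.null(x$true_risk)) cat("  true risks attached (simulation cohort)\n")
  invisible(x)
}

# Row-subset a cohort (bootstrap resamples, random splits). Indices may
# repeat; no re-validation — a degenerate resample is the fitting strategy's
# business to detect and report.
cohort_subset <- function(cohort, idx) {
  structure(
    list(X = cohort$X[idx, , drop = FALSE],
         y = cohort$y[idx],
         ids = cohort$ids[idx],
         subgroup = if (is.null(cohort$subgroup)) NULL else cohort$subgroup[idx],
         true_risk = if (is.null(cohort$true_risk)) NULL else cohort$true_risk[idx],
         n = length(idx), p = cohort$p,
         n_events = sum(cohort$y[idx]),
         prevalence = mean(cohort$y[idx])),
    class = "predstab_cohort")
}
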