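#' Assemble a full stability report from a bootstrap run
#'
#' Bundles every instability summary into one object: per-individual MAPE
#' and its average, stability intervals with smoothed bounds, classification
#' instability indices per requested threshold, the original and bootstrap
#' c-statistics, and (when subgroup labels are available) the same report
#' recomputed within each subgroup.
#'
#' @param run A `predstab_run`.
#' @param y 0/1 outcomes of the original cohort.
#' @param thresholds Optional vector of classification thresholds in (0, 1);
#'   there is no default threshold because it is a clinical choice.
#' @param level,span Passed to [stability_intervals()].
#' @param subgroups Optional vector of subgroup labels (one per individual);
#'   triggers [subgroup_stability()].
#' @return An object of class `predstab_report`.
#' @examples
#' co <- generate_simulation_cohort(150, seed = 3)
#' run <- run_stability_bootstrap(co, strategy_logistic(), B = 60, seed = 3)
#' rep <- stability_report(run, co$y, thresholds = 0.5)
#' rep$average_mape
#' @export
stability_report <- function(run, y, thresholds = NULL, level = 0.95,
                             span = 0.5, subgroups = NULL) {
  stopifnot(inherits(run, "predstab_run"))
  mape <- mape_per_individual(run)
  intervals <- stability_intervals(run, level = level, span = span)
  cls <- NULL
  if (!is.null(thresholds)) {
    cls <- lapply(thresholds, function(t)
      classification_instability_index(run, t))
    names(cls) <- as.character(thresholds)
  }
  # a slice (e.g., a small subgroup) may contain a single outcome class;
  # discrimination is undefined there and reported as NA
  c_ok <- sum(y == 1) > 0 && sum(y == 0) > 0
  c_orig <- if (c_ok) c_statistic(run$p_orig, y) else NA_real_
  c_boot <- if (c_ok) bootstrap_c_distribution(run, y) else
    structure(rep(NA_real_, run$B),
              summary = c(min = NA_real_, p2.5 = NA_real_, median = NA_real_,
                          p97.5 = NA_real_, max = NA_real_))
  sub <- NULL
  if (!is.null(subgroups))
    sub <- subgroup_stability(run, y, subgroups,
                              thresholds = thresholds, level = level,
                              span = span)
  structure(
    list(mape = mape,
         average_mape = mean(mape),
         intervals = intervals,
         class_instability = cls,
         thresholds = thresholds,
         c_orig = c_orig,
         c_boot = c_boot,
         n = length(run$p_orig),
         B = run$B,
         subgroup_reports = sub),
    class = "predstab_report")
}

#' @export
print.predstab_report <- function(x, ...) {
  cat("<predstab_report>\n")
  cat(sprintf("  N = %d individuals, B = %d bootstrap models\n", x$n, x$B))
  cat(sprintf("  average MAPE = %.4f (per-individual range %.4f-%.4f)\n",
              x$average_mape, min(x$mape), max(x$mape)))
  s <- attr(x$c_boot, "summary")
  cat(sprintf("  c-statistic: original %.3f; bootstrap 2.5th-97.5th pct %.3f-%.3f\n",
              x$c_orig, s[["p2.5"]], s[["p97.5"]]))
  if (!is.null(x$class_instability))
    for (t in names(x$class_instability))
      cat(sprintf("  classification instability at threshold %s: mean %.3f, max %.3f\n",
                  t, mean(x$class_instability[[t]]),
                  max(x$class_instability[[t]])))
  if (!is.null(x$subgroup_reports))
    for (lv in names(x$subgroup_reports))
      cat(sprintf("  subgroup '%s': average MAPE %.4f (n = %d)\n", lv,
                  x$subgroup_reports[[lv]]$average_mape,
                  x$subgroup_reports[[lv]]$n))
  invisible(x)
}

report_to_list <- function(run, report) {
  sub <- NULL
  if (!is.null(report$subgroup_reports))
    sub <- lapply(report$subgroup_reports, function(r) list(
      n = r$n,
      average_mape = r$average_mape,
      mape_quantiles = as.list(quantile(r$mape, c(0.025, 0.5, 0.975),
                                        type = 7)),
      c_orig = r$c_orig,
      c_boot_summary = as.list(attr(r$c_boot, "summary"))))
  list(
    schema = "predstab_stability_report_v1",
    provenance = list(
      strategy = strategy_to_list(run$spec),
      master_seed = run$master_seed,
      B_requested = run$B_requested,
      B_successful = run$B,
      failures = run$failures),
    n = report$n,
    average_mape = report$average_mape,
    mape_quantiles = as.list(quantile(report$mape, c(0.025, 0.5, 0.975),
                                      type = 7)),
    mape_by_id = as.list(report$mape),
    c_orig = report$c_orig,
    c_boot_summary = as.list(attr(report$c_boot, "summary")),
    classification_instability = if (is.null(report$class_instability)) NULL
      else lapply(report$class_instability, function(v)
        list(mean = mean(v), max = max(v))),
    subgroups = sub)
}

#' Serialize a stability report to JSON (plus readable text summary)
#'
#' Writes a single JSON document holding the instability summaries and full
#' provenance (strategy recipe, seeds, replicate failures), and a `.txt`
#' sidecar with the printed summary. The JSON structure follows the schema
#' shipped at `system.file("schema", "stability_report_schema.json",
#' package = "predstab")`.
#'
#' @param run A `predstab_run`.
#' @param report The matching `predstab_report`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(run, report, path) {
  stopifnot(inherits(run, "predstab_run"), inherits(report, "predstab_report"))
  obj <- report_to_list(run, report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  sink(con); on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(path)
}

#' Read back a serialized stability report
#'
#' @param path Path written by [write_stability_report()].
#' @return The parsed report list (as written; not a `predstab_report`).
#' @export
read_stability_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Structurally validate a serialized report against the shipped schema
#'
#' Checks that every required field in the package's report schema is
#' present with the declared JSON type.
#'
#' @param path Path to a report JSON file.
#' @return `TRUE` invisibly, or an error listing missing/mistyped fields.
#' @export
validate_report_schema <- function(path) {
  schema_path <- system.file("schema", "stability_report_schema.json",
                             package = "predstab")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  problems <- character(0)
  check <- function(node, spec, prefix) {
    for (field in names(spec$required)) {
      want <- spec$required[[field]]
      if (is.null(node[[field]])) {
        problems <<- c(problems, paste0(prefix, field, ": missing"))
        next
      }
      type_ok <- switch(want$type,
        number = is.numeric(node[[field]]) ||
          (is.list(node[[field]]) && all(vapply(node[[field]], is.numeric, logical(1)))),
        string = is.character(node[[field]]),
        object = is.list(node[[field]]),
        TRUE)
      if (!type_ok)
        problems <<- c(problems,
                       paste0(prefix, field, ": expected ", want$type))
      if (!is.null(want$required) && is.list(node[[field]]))
        check(node[[field]], want, paste0(prefix, field, "."))
    }
  }
  check(obj, schema, "")
  if (length(problems))
    stop("report schema violations:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}
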