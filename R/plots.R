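#' Render the instability plot suite
#'
#' Writes the six standard instability visualizations, one PNG per
#' requested kind, each accompanied by a CSV of its underlying data (so
#' downstream checks compare data, not pixels):
#' \describe{
#'   \item{`prediction`}{scatter of every bootstrap prediction against the
#'     original prediction, with the smoothed 95% stability-interval bounds
#'     and the 45-degree identity line.}
#'   \item{`calibration`}{spaghetti of bootstrap-model calibration curves in
#'     the original data (a seeded random subsample of `curve_sample`
#'     curves), with the original model's curve emphasized.}
#'   \item{`mape`}{per-individual MAPE against original prediction.}
#'   \item{`classification`}{classification instability index against
#'     original prediction, one file per threshold (thresholds must be
#'     supplied via `report`; there is no default).}
#'   \item{`decision`}{decision-curve spaghetti (bootstrap models,
#'     subsampled) with the original model, treat-all and treat-none
#'     references.}
#'   \item{`cstat`}{histogram of the bootstrap c-statistic distribution
#'     with the original c marked.}
#' }
#'
#' @param run A `predstab_run`.
#' @param report The matching `predstab_report` (same N and B).
#' @param y 0/1 outcomes of the original cohort.
#' @param kinds Character vector of plot kinds (default: all six).
#' @param out_dir Output directory (created if needed).
#' @param curve_sample Maximum number of bootstrap curves drawn on the
#'   calibration and decision spaghetti plots.
#' @param decision_thresholds Threshold grid for the decision curves.
#' @param seed Seed for the curve subsampling.
#' @return Invisibly, a named list mapping kind to the written image path.
#' @export
render_instability_plots <- function(run, report, y,
                                     kinds = c("prediction", "calibration",
                                               "mape", "classification",
                                               "decision", "cstat"),
                                     out_dir = ".",
                                     curve_sample = 200,
                                     decision_thresholds = seq(0.01, 0.50,
                                                               by = 0.01),
                                     seed = 1) {
  stopifnot(inherits(run, "predstab_run"), inherits(report, "predstab_report"))
  if (length(run$p_orig) != report$n || run$B != report$B)
    stop("run and report disagree on N or B", call. = FALSE)
  valid <- c("prediction", "calibration", "mape", "classification",
             "decision", "cstat")
  bad <- setdiff(kinds, valid)
  if (length(bad))
    stop("unknown plot kind(s): ", paste(bad, collapse = ", "),
         "; valid kinds: ", paste(valid, collapse = ", "), call. = FALSE)
  if ("classification" %in% kinds && is.null(report$class_instability))
    stop("classification plot requested but the report carries no thresholds; ",
         "rebuild the report with `thresholds = ...` (a clinical choice, no default)",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- list()
  emit <- function(kind, plot, data) {
    img <- file.path(out_dir, paste0(kind, ".png"))
    csv <- file.path(out_dir, paste0(kind, ".csv"))
    ggplot2::ggsave(img, plot, width = 6.5, height = 5, dpi = 120)
    write.csv(data, csv, row.names = FALSE)
    paths[[kind]] <<- img
  }
  B <- run$B
  keep <- with_seed(seed, sample.int(B, min(curve_sample, B)))

  if ("prediction" %in% kinds) {
    long <- data.frame(
      p_orig = rep(run$p_orig, each = B),
      p_boot = as.vector(run$P_boot))
    sm <- report$intervals$individual
    gp <- ggplot2::ggplot(long, ggplot2::aes(x = .data$p_orig, y = .data$p_boot)) +
      ggplot2::geom_point(alpha = 0.05, size = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
      ggplot2::geom_line(data = sm[order(sm$p_orig), ],
                         ggplot2::aes(y = .data$lower_smooth), colour = "blue") +
      ggplot2::geom_line(data = sm[order(sm$p_orig), ],
                         ggplot2::aes(y = .data$upper_smooth), colour = "blue") +
      ggplot2::labs(x = "Original model prediction",
                    y = "Bootstrap model predictions",
                    title = "Prediction instability") +
      ggplot2::theme_minimal()
    emit("prediction", gp, cbind(id = rep(run$ids, each = B), long))
  }

  if ("calibration" %in% kinds) {
    curves <- lapply(keep, function(b) {
      cc <- calibration_curve(run$P_boot[b, ], y)
      data.frame(source = paste0("boot", b), grid = cc$grid,
                 observed = cc$observed)
    })
    cc0 <- calibration_curve(run$p_orig, y)
    dat <- rbind(do.call(rbind, curves),
                 data.frame(source = "original", grid = cc0$grid,
                            observed = cc0$observed))
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$grid, y = .data$observed,
                                            group = .data$source)) +
      ggplot2::geom_line(data = dat[dat$source != "original", ],
                         alpha = 0.15, colour = "grey40") +
      ggplot2::geom_line(data = dat[dat$source == "original", ],
                         colour = "red", linewidth = 1) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "Estimated risk", y = "Smoothed observed risk",
                    title = "Calibration instability") +
      ggplot2::theme_minimal()
    emit("calibration", gp, dat)
  }

  if ("mape" %in% kinds) {
    dat <- data.frame(id = run$ids, p_orig = run$p_orig, mape = report$mape)
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$p_orig, y = .data$mape)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.6) +
      ggplot2::labs(x = "Original model prediction", y = "Individual MAPE",
                    title = sprintf("MAPE instability (average %.4f)",
                                    report$average_mape)) +
      ggplot2::theme_minimal()
    emit("mape", gp, dat)
  }

  if ("classification" %in% kinds) {
    for (t in names(report$class_instability)) {
      dat <- data.frame(id = run$ids, p_orig = run$p_orig,
                        instability = report$class_instability[[t]],
                        threshold = as.numeric(t))
      gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$p_orig,
                                              y = .data$instability)) +
        ggplot2::geom_point(alpha = 0.5, size = 0.6) +
        ggplot2::geom_vline(xintercept = as.numeric(t), linetype = 2) +
        ggplot2::ylim(0, 1) +
        ggplot2::labs(x = "Original model prediction",
                      y = "Classification instability index",
                      title = sprintf("Classification instability (threshold %s)", t)) +
        ggplot2::theme_minimal()
      kind_t <- if (length(report$class_instability) == 1L) "classification"
                else paste0("classification_", t)
      emit(kind_t, gp, dat)
    }
  }

  if ("decision" %in% kinds) {
    curves <- lapply(keep, function(b) {
      nb <- net_benefit_curve(run$P_boot[b, ], y, decision_thresholds)
      data.frame(source = paste0("boot", b), threshold = nb$threshold,
                 nb = nb$nb_model)
    })
    nb0 <- net_benefit_curve(run$p_orig, y, decision_thresholds)
    dat <- rbind(do.call(rbind, curves),
                 data.frame(source = "original", threshold = nb0$threshold,
                            nb = nb0$nb_model),
                 data.frame(source = "treat_all", threshold = nb0$threshold,
                            nb = nb0$nb_treat_all),
                 data.frame(source = "treat_none", threshold = nb0$threshold,
                            nb = 0))
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                            group = .data$source)) +
      ggplot2::geom_line(data = dat[grepl("^boot", dat$source), ],
                         alpha = 0.15, colour = "grey40") +
      ggplot2::geom_line(data = dat[dat$source == "original", ],
                         colour = "red", linewidth = 1) +
      ggplot2::geom_line(data = dat[dat$source == "treat_all", ],
                         colour = "blue", linetype = 2) +
      ggplot2::geom_line(data = dat[dat$source == "treat_none", ],
                         colour = "black", linetype = 3) +
      ggplot2::coord_cartesian(ylim = c(-0.05, max(dat$nb) + 0.02)) +
      ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                    title = "Decision curve instability") +
      ggplot2::theme_minimal()
    emit("decision", gp, dat)
  }

  if ("cstat" %in% kinds) {
    dat <- data.frame(c_boot = as.vector(report$c_boot))
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$c_boot)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "white") +
      ggplot2::geom_vline(xintercept = report$c_orig, colour = "red") +
      ggplot2::labs(x = "Bootstrap model c-statistic", y = "Count",
                    title = sprintf("c-statistic instability (original %.3f)",
                                    report$c_orig)) +
      ggplot2::theme_minimal()
    emit("cstat", gp, dat)
  }

  invisible(paths)
}
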