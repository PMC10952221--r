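make_small_assessment <- function(n = 150, B = 50, seed = 15) {
  co <- quick_cohort(n, seed = seed)
  run <- suppressWarnings(
    run_stability_bootstrap(co, strategy_logistic(), B = B, seed = seed,
                            failure_cap = 0.25))
  list(co = co,
       run = run,
       report = stability_report(run, co$y, thresholds = 0.5))
}

test_that("all six plot kinds are rendered with data sidecars", {
  a <- make_small_assessment()
  out <- withr::local_tempdir()
  paths <- render_instability_plots(a$run, a$report, a$co$y, out_dir = out,
                                    curve_sample = 30, seed = 2)
  expect_length(paths, 6)
  for (p in paths) expect_true(file.exists(p))
  csvs <- list.files(out, pattern = "\\.csv$")
  expect_length(csvs, 6)
  # calibration spaghetti holds min(curve_sample, B) bootstrap curves + the
  # original
  cal <- read.csv(file.path(out, "calibration.csv"))
  expect_equal(length(unique(cal$source)), min(30, a$run$B) + 1L)
  expect_true("original" %in% cal$source)
  # decision data includes the reference strategies
  dec <- read.csv(file.path(out, "decision.csv"))
  expect_true(all(c("original", "treat_all", "treat_none") %in% dec$source))
})

test_that("curve subsampling is seeded and plots fail on bad requests", {
  a <- make_small_assessment()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  render_instability_plots(a$run, a$report, a$co$y, kinds = "calibration",
                           out_dir = out1, curve_sample = 10, seed = 7)
  render_instability_plots(a$run, a$report, a$co$y, kinds = "calibration",
                           out_dir = out2, curve_sample = 10, seed = 7)
  expect_identical(readLines(file.path(out1, "calibration.csv")),
                   readLines(file.path(out2, "calibration.csv")))
  expect_error(
    render_instability_plots(a$run, a$report, a$co$y, kinds = "volcano",
                             out_dir = out1),
    "valid kinds")
  rep_nothresh <- stability_report(a$run, a$co$y)
  expect_error(
    render_instability_plots(a$run, rep_nothresh, a$co$y,
                             kinds = "classification", out_dir = out1),
    "threshold")
})

test_that("a degenerate run scatters on the identity line", {
  set.seed(8)
  p <- runif(20)
  run <- fake_run(p, matrix(rep(p, 10), nrow = 10, byrow = TRUE))
  y <- rbinom(20, 1, p); y[1:2] <- c(0, 1)
  report <- suppressWarnings(stability_report(run, y))
  out <- withr::local_tempdir()
  render_instability_plots(run, report, y, kinds = "prediction",
                           out_dir = out)
  dat <- read.csv(file.path(out, "prediction.csv"))
  expect_equal(dat$p_boot, dat$p_orig)
})

test_that("serialized reports round-trip and validate against the schema", {
  a <- make_small_assessment()
  path <- file.path(withr::local_tempdir(), "report.json")
  write_stability_report(a$run, a$report, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("json$", "txt", path)))
  back <- read_stability_report(path)
  # cross-module consistency at full precision
  expect_equal(back$average_mape, average_mape(a$run))
  expect_equal(back$c_orig, a$report$c_orig)
  expect_equal(back$n, a$report$n)
  expect_equal(back$provenance$B_successful, a$run$B)
  expect_equal(back$provenance$master_seed, a$run$master_seed)
  expect_equal(back$provenance$strategy$kind, "unpenalized_logistic")
  expect_true(validate_report_schema(path))
})

test_that("replicate failures appear verbatim in the report provenance", {
  set.seed(1)
  d <- data.frame(y = rbinom(30, 1, 0.5), x1 = rnorm(30), x2 = rnorm(30))
  d$x1 <- d$x1 + d$y  # moderate signal so the original fit succeeds
  co <- validate_cohort(d, outcome = "y")
  run <- suppressWarnings(
    run_stability_bootstrap(co, strategy_uniform_shrinkage(), B = 80,
                            seed = 2, failure_cap = 1))
  report <- stability_report(run, co$y)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_stability_report(run, report, path)
  back <- read_stability_report(path)
  expect_equal(nrow(back$provenance$failures), nrow(run$failures))
  if (nrow(run$failures) > 0)
    expect_identical(back$provenance$failures$reason, run$failures$reason)
})

test_that("the command-line entry point script is shipped", {
  cli <- system.file("cli", "predstab.R", package = "predstab")
  expect_true(nzchar(cli) && file.exists(cli))
})
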