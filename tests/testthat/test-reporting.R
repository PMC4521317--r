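# CSV/YAML I/O, report rendering, and the command-line interface.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_lab_csv validates the header and drops malformed rows", {
  f <- write_lines_tmp(c(
    "patient_id,day,variable,value",
    "A,1,sodium,140", "A,1,sodium,138", "B,2,sodium,135", "B,1,wbc,9.5"
  ))
  obs <- read_lab_csv(f, quiet = TRUE)
  expect_equal(nrow(obs), 4)
  expect_type(obs$day, "integer")
  expect_type(obs$value, "double")

  f2 <- write_lines_tmp(c(
    "patient_id,day,variable,value",
    "A,1,sodium,140", "A,1,sodium,NA", "B,0,sodium,135"
  ))
  expect_message(obs2 <- read_lab_csv(f2), "Dropped 2")
  expect_equal(nrow(obs2), 1)

  f3 <- write_lines_tmp(c("id,day,variable,value", "A,1,x,1"))
  expect_error(read_lab_csv(f3, quiet = TRUE), "patient_id")
  f4 <- write_lines_tmp(c("A,1,x,1"))
  expect_error(read_lab_csv(f4, quiet = TRUE), "Invalid header")
  expect_error(read_lab_csv("does-not-exist.csv"), "not found")
})

test_that("lab CSVs round-trip through write and read", {
  sim <- default_icu_specs(n_patients = 50, seed = 3)
  obs <- simulate_cohort(sim$specs, sim$config)
  f <- withr::local_tempfile(fileext = ".csv")
  write_lab_csv(obs, f)
  back <- read_lab_csv(f, quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(obs), tolerance = 1e-12)
})

test_that("cohort YAML overrides defaults and requires a seed", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "n_patients: 40",
    "variables:",
    "  - name: a",
    "    marginal_family: normal",
    "    location: 0",
    "    scale: 1",
    "    temporal_rho: 0.9",
    "  - name: b",
    "    marginal_family: lognormal",
    "    location: 0.5",
    "    scale: 0.4",
    "cross_correlation:",
    "  - [a, b, 0.6]"
  ), f)
  sim <- read_cohort_yaml(f)
  expect_equal(nrow(sim$specs), 2)
  expect_equal(sim$config$cross_correlation["a", "b"], 0.6)
  expect_equal(sim$config$n_patients, 40L)
  obs <- simulate_cohort(sim$specs, sim$config)
  expect_true(all(obs$value[obs$variable == "b"] > 0))

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_patients: 10", f2)
  expect_error(read_cohort_yaml(f2), "seed")
})

test_that("analysis YAML maps onto run_config with canonical defaults", {
  defaults <- run_config()
  expect_equal(defaults$n_bins, 20L)
  expect_equal(defaults$lower_pct, 0.01)
  expect_equal(defaults$upper_pct, 0.99)
  expect_equal(defaults$day_pairs, list(c(1L, 2L), c(2L, 3L)))
  expect_equal(length(defaults$variable_pairs), 4)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_bins: 16", "pooling: per_day"), f)
  cfg <- read_run_yaml(f)
  expect_equal(cfg$n_bins, 16L)
  expect_equal(cfg$pooling, "per_day")
  expect_equal(cfg$lower_pct, defaults$lower_pct)
})

test_that("render_report writes the results table, figures, and summary", {
  fit <- default_analysis()
  dir <- withr::local_tempdir()
  files <- render_report(fit, dir)
  expect_setequal(basename(files),
                  c("results.csv", "daily_information.png",
                    "pair_redundancy.png", "summary.txt"))
  expect_true(all(file.exists(files)))
  summary_txt <- readLines(file.path(dir, "summary.txt"))
  expect_true(any(grepl("Most redundant", summary_txt)))
  expect_error(render_report(tidy(fit)[0, ], dir, n_bins = 20), "empty")
})

test_that("figure dashed line sits at log2(n_bins)", {
  res <- tidy(default_analysis())
  p16 <- plot_daily_information(res, n_bins = 16)
  hline <- p16$layers[[2]]$data$yintercept %||%
    ggplot2::layer_data(p16, 2)$yintercept[1]
  expect_equal(unname(hline), 4.0)
  p <- plot_pair_redundancy(res, n_bins = 20)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(default_analysis(), type = "pairs"), "ggplot")
})

test_that("the CLI chains simulate, analyze, and report deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  args <- function(d) c("run", "--output-dir", d, "--seed", "7",
                        "--n-patients", "300")
  expect_equal(suppressMessages(icuinfo_main(args(dir1))), 0L)
  expect_equal(suppressMessages(icuinfo_main(args(dir2))), 0L)
  expect_identical(readLines(file.path(dir1, "results.csv")),
                   readLines(file.path(dir2, "results.csv")))
  expect_true(file.exists(file.path(dir1, "summary.txt")))

  # analyze runs on simulate output
  out <- withr::local_tempfile(fileext = ".csv")
  res <- withr::local_tempfile(fileext = ".csv")
  expect_equal(suppressMessages(icuinfo_main(
    c("simulate", "--out", out, "--seed", "9", "--n-patients", "200")
  )), 0L)
  expect_equal(suppressMessages(icuinfo_main(
    c("analyze", "--input", out, "--out", res)
  )), 0L)
  expect_gt(nrow(readr::read_csv(res, show_col_types = FALSE)), 0)

  # failures exit nonzero with a message
  expect_equal(suppressMessages(icuinfo_main(
    c("analyze", "--input", "missing.csv", "--out", res)
  )), 1L)
  expect_equal(suppressMessages(icuinfo_main("frobnicate")), 1L)
})
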