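# Gaussian-copula cohort generator: determinism, marginals, coupling,
# attrition, and input validation.

test_that("degenerate configurations are handled or rejected", {
  specs <- dplyr::bind_rows(
    variable_spec("a", "normal", 0, 1),
    variable_spec("b", "normal", 0, 1)
  )
  expect_equal(nrow(simulate_cohort(specs, cohort_config(0, seed = 1))), 0)

  bad_R <- matrix(c(1, 0.9, 0.9, 1), 2)
  bad_R[1, 2] <- bad_R[2, 1] <- 1.5 # not PSD
  expect_error(simulate_cohort(specs, cohort_config(10, cross_correlation = bad_R, seed = 1)),
               "smallest eigenvalue")
  expect_error(cohort_config(10, measurements_per_day = c(4, 1)),
               "lo <= hi")
  expect_error(cohort_config(10, attrition = c(0.5, 0.5, 0.5)), "start at 1")
  expect_error(variable_spec("a", "normal", 0, -1), "scale")
  expect_error(variable_spec("a", "normal", 0, 1, temporal_rho = 1), "temporal_rho")
})

test_that("the same seed and configuration reproduce the cohort byte for byte", {
  sim <- default_icu_specs(n_patients = 200, seed = 7)
  a <- simulate_cohort(sim$specs, sim$config)
  b <- simulate_cohort(sim$specs, sim$config)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_lab_csv(a, f1)
  write_lab_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the data
  sim2 <- default_icu_specs(n_patients = 200, seed = 8)
  expect_false(identical(a, simulate_cohort(sim2$specs, sim2$config)))
})

test_that("configured cross-correlation is recovered in generated day-1 values", {
  specs <- dplyr::bind_rows(
    variable_spec("a", "normal", 0, 1),
    variable_spec("b", "normal", 0, 1)
  )
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  config <- cohort_config(5000, n_days = 1, cross_correlation = R,
                          attrition = 1, measurements_per_day = c(1L, 1L),
                          seed = 3)
  obs <- simulate_cohort(specs, config)
  wide <- tidyr::pivot_wider(obs, names_from = "variable", values_from = "value")
  expect_gt(stats::cor(wide$a, wide$b), 0.85)
  expect_lt(stats::cor(wide$a, wide$b), 0.95)
})

test_that("sample coupling is monotone in the configured correlation", {
  cors <- vapply(c(0.0, 0.5, 0.9), function(r) {
    specs <- dplyr::bind_rows(
      variable_spec("a", "normal", 0, 1),
      variable_spec("b", "normal", 0, 1)
    )
    config <- cohort_config(5000, n_days = 1,
                            cross_correlation = matrix(c(1, r, r, 1), 2),
                            attrition = 1, measurements_per_day = c(1L, 1L),
                            seed = 13)
    wide <- tidyr::pivot_wider(simulate_cohort(specs, config),
                               names_from = "variable", values_from = "value")
    stats::cor(wide$a, wide$b)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("attrition is monotone dropout: later-day patients are a subset", {
  obs <- default_cohort()
  by_day <- split(unique(obs[, c("patient_id", "day")])$patient_id,
                  unique(obs[, c("patient_id", "day")])$day)
  expect_true(all(by_day[["2"]] %in% by_day[["1"]]))
  expect_true(all(by_day[["3"]] %in% by_day[["2"]]))
  # default attrition lands near 68% and 46% of the day-1 cohort
  frac <- lengths(by_day) / lengths(by_day)[1]
  expect_equal(unname(frac[2]), 0.68, tolerance = 0.05)
  expect_equal(unname(frac[3]), 0.46, tolerance = 0.08)
})

test_that("default panel reproduces its target day-1 moments", {
  obs <- default_cohort()
  sim <- default_sim()
  day1 <- daily_median(obs) |> dplyr::filter(day == 1)
  stats_tbl <- day1 |>
    dplyr::group_by(variable) |>
    dplyr::summarise(m = mean(median_value), s = stats::sd(median_value))

  targets <- tibble::tribble(
    ~variable, ~mean, ~sd,
    "hematocrit", 31.9, 5.0,
    "platelet", 218.4, 112.2,
    "wbc", 12.3, 8.8,
    "glucose", 139.3, 50.5,
    "hco3", 24.4, 4.6,
    "potassium", 4.1, 0.5,
    "sodium", 138.6, 4.4,
    "chloride", 105.5, 5.7,
    "bun", 25.3, 20.9,
    "creatinine", 1.4, 1.5,
    "lactate", 2.5, 2.0
  )
  joined <- dplyr::inner_join(stats_tbl, targets, by = "variable")
  expect_equal(nrow(joined), 11)
  expect_true(all(abs(joined$m - joined$mean) <= 0.2 * joined$mean))
  expect_true(all(abs(joined$s - joined$sd) <= 0.2 * joined$sd))

  # headline spot checks in natural units
  expect_equal(joined$m[joined$variable == "sodium"], 138.6, tolerance = 2.0 / 138.6)
  expect_lt(abs(joined$s[joined$variable == "creatinine"] - 1.5), 0.5)

  # lognormal support: strictly positive values
  skewed <- sim$specs$name[sim$specs$marginal_family == "lognormal"]
  expect_true(all(obs$value[obs$variable %in% skewed] > 0))

  # lactate is the least frequently measured variable
  counts <- dplyr::count(day1, variable)
  expect_equal(counts$variable[which.min(counts$n)], "lactate")
})

test_that("raw measurements per patient-day-variable stay within the configured range", {
  obs <- default_cohort()
  k <- obs |>
    dplyr::count(patient_id, day, variable) |>
    dplyr::pull(n)
  expect_true(all(k >= 1 & k <= 4))
  expect_gt(length(unique(k)), 1)
})
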