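# Shared fixtures, generated once per test run and cached. The default
# cohort (5000 patients, seed 101) is the study-condition fixture used by
# the recovery and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    sim <- default_icu_specs(n_patients = 5000, seed = 101)
    .fixture_env$sim <- sim
    .fixture_env$cohort <- simulate_cohort(sim$specs, sim$config)
  }
  .fixture_env$cohort
}

default_sim <- function() {
  default_cohort()
  .fixture_env$sim
}

default_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    .fixture_env$analysis <- suppressWarnings(
      run_full_analysis(default_cohort(), run_config())
    )
  }
  .fixture_env$analysis
}

# small deterministic two-variable cohort for targeted persistence checks
two_var_cohort <- function(rho_a = 0.95, rho_b = 0.2, n = 5000, seed = 7,
                           cross = 0, noise = 0, n_days = 2) {
  specs <- dplyr::bind_rows(
    variable_spec("a", "normal", 0, 1, temporal_rho = rho_a, noise_sd = noise),
    variable_spec("b", "normal", 0, 1, temporal_rho = rho_b, noise_sd = noise)
  )
  R <- matrix(c(1, cross, cross, 1), 2)
  config <- cohort_config(n, n_days = n_days, cross_correlation = R,
                          attrition = rep(1, n_days), seed = seed)
  list(specs = specs, config = config,
       obs = simulate_cohort(specs, config))
}

random_joint_table <- function(nr, nc) {
  m <- matrix(stats::rexp(nr * nc), nr, nc)
  m / sum(m)
}
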