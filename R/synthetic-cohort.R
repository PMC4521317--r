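# Synthetic longitudinal ICU lab cohort: a Gaussian copula couples the 11
# variables within a day, a per-variable AR(1) on the latent scale carries
# information across days, marginals are normal or lognormal, patients drop
# out monotonically (discharge), and each retained patient-day-variable
# emits 1-4 noisy raw measurements around its latent daily value.

#' Specify one synthetic lab variable
#'
#' @param name Variable identifier (e.g. `"creatinine"`).
#' @param marginal_family `"normal"` or `"lognormal"`. For `"normal"`,
#'   `location`/`scale` are the mean and SD in natural units; for
#'   `"lognormal"` they are the log-scale mean and SD (so all generated
#'   values are positive).
#' @param location,scale Marginal parameters (see `marginal_family`);
#'   `scale` must be positive.
#' @param temporal_rho AR(1) correlation of the latent process between
#'   consecutive days, in `[0, 1)`. High values make the variable persistent
#'   (little novel information day over day).
#' @param noise_sd Within-day measurement noise SD in natural units
#'   (non-negative); raw measurements scatter around the daily latent value.
#' @return A one-row tibble describing the variable.
#' @export
variable_spec <- function(name, marginal_family = c("normal", "lognormal"),
                          location, scale, temporal_rho = 0.5, noise_sd = 0) {
  marginal_family <- match.arg(marginal_family)
  if (scale <= 0) abort("`scale` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (temporal_rho < 0 || temporal_rho >= 1) {
    abort("`temporal_rho` must lie in [0, 1).")
  }
  tibble::tibble(
    name = name, marginal_family = marginal_family,
    location = location, scale = scale,
    temporal_rho = temporal_rho, noise_sd = noise_sd
  )
}

#' Configure a synthetic cohort
#'
#' @param n_patients Number of patients admitted on day 1.
#' @param n_days Number of ICU days to simulate (default 3).
#' @param cross_correlation Symmetric positive semi-definite correlation
#'   matrix (unit diagonal) of the latent Gaussian copula, one row/column per
#'   variable, in the order the variable specs are supplied. `NULL` means
#'   independence.
#' @param attrition Numeric vector of length `n_days`: fraction of the day-1
#'   cohort still present on each day. Must start at 1; dropout is monotone
#'   (a discharged patient emits nothing afterwards).
#' @param measurements_per_day Integer range `c(lo, hi)`: each retained
#'   patient-day-variable receives between `lo` and `hi` raw measurements,
#'   uniformly.
#' @param missing_rate Probability that a patient-day-variable is unmeasured;
#'   a scalar, or a named vector with one entry per variable.
#' @param seed RNG seed; the same seed and configuration reproduce the cohort
#'   exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, n_days = 3, cross_correlation = NULL,
                          attrition = rep(1, n_days),
                          measurements_per_day = c(1L, 4L),
                          missing_rate = 0, seed = 1L) {
  if (n_patients < 0) abort("`n_patients` must be non-negative.")
  if (n_days < 1) abort("`n_days` must be at least 1.")
  if (length(attrition) != n_days || attrition[1] != 1 ||
      any(attrition <= 0) || any(attrition > 1)) {
    abort("`attrition` must have length `n_days`, start at 1, with entries in (0, 1].")
  }
  if (length(measurements_per_day) != 2 ||
      measurements_per_day[1] > measurements_per_day[2] ||
      measurements_per_day[1] < 1) {
    abort("`measurements_per_day` must be c(lo, hi) with 1 <= lo <= hi.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_days = as.integer(n_days),
      cross_correlation = cross_correlation, attrition = attrition,
      measurements_per_day = as.integer(measurements_per_day),
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

check_correlation_matrix <- function(R, p) {
  if (is.null(R)) return(diag(p))
  R <- as.matrix(R)
  if (nrow(R) != p || ncol(R) != p) {
    abort(sprintf("`cross_correlation` must be %d x %d to match the variable specs.", p, p))
  }
  if (max(abs(R - t(R))) > 1e-10) abort("`cross_correlation` must be symmetric.")
  if (max(abs(diag(R) - 1)) > 1e-10) abort("`cross_correlation` must have a unit diagonal.")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "`cross_correlation` is not positive semi-definite (smallest eigenvalue %.6g).",
      min(ev)
    ))
  }
  R
}

#' Generate a synthetic longitudinal ICU lab cohort
#'
#' Each patient's day-1 latent vector is drawn from a multivariate standard
#' normal with the configured cross-correlation; subsequent days evolve
#' per-variable as AR(1) with `temporal_rho`, with innovations re-coupled
#' through the same cross-correlation so the same-day structure is preserved.
#' Latent values are mapped through each variable's marginal, and each
#' retained patient-day-variable emits `Uniform{lo..hi}` raw measurements:
#' the daily latent value plus independent Gaussian noise (`noise_sd`).
#' Patients drop out between days per `attrition` and never return;
#' `missing_rate` independently silences individual patient-day-variables.
#'
#' @param specs Tibble of variable specifications ([variable_spec()] rows).
#' @param config A [cohort_config()].
#' @return Tibble of raw observations with columns `patient_id`, `day`,
#'   `variable`, `value`, sorted by (patient_id, day, variable).
#' @examples
#' specs <- dplyr::bind_rows(
#'   variable_spec("a", "normal", 0, 1, temporal_rho = 0.9),
#'   variable_spec("b", "normal", 0, 1, temporal_rho = 0.2)
#' )
#' obs <- simulate_cohort(specs, cohort_config(50, seed = 7))
#' @export
simulate_cohort <- function(specs, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(specs) == 0) abort("`specs` must contain at least one variable.")
  p <- nrow(specs)
  R <- check_correlation_matrix(config$cross_correlation, p)
  miss <- missing_rate_vector(config$missing_rate, specs$name)

  empty <- tibble::tibble(
    patient_id = character(), day = integer(),
    variable = character(), value = double()
  )
  if (config$n_patients == 0) return(empty)

  withr::local_seed(config$seed)
  n <- config$n_patients
  D <- config$n_days
  # square root of R via eigen decomposition (chol fails on singular PSD)
  ed <- eigen(R, symmetric = TRUE)
  A <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p) %*% t(ed$vectors)
  rho <- specs$temporal_rho
  lo <- config$measurements_per_day[1]
  hi <- config$measurements_per_day[2]
  ids <- sprintf("P%0*d", nchar(as.character(n)), seq_len(n))

  z <- matrix(rnorm(n * p), n, p) %*% A
  present <- rep(TRUE, n)
  out <- vector("list", D)
  for (d in seq_len(D)) {
    if (d > 1) {
      innov <- matrix(rnorm(n * p), n, p) %*% A
      z <- sweep(z, 2, rho, `*`) +
        sweep(innov, 2, sqrt(1 - rho^2), `*`)
      surv <- config$attrition[d] / config$attrition[d - 1]
      present <- present & (runif(n) < surv)
    }
    measured <- matrix(runif(n * p), n, p) >=
      matrix(miss, n, p, byrow = TRUE)
    k <- if (lo == hi) {
      matrix(lo, n, p)
    } else {
      matrix(sample(lo:hi, n * p, replace = TRUE), n, p)
    }
    daily <- latent_to_natural(z, specs)
    keep <- which(present & measured, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    counts <- k[keep]
    vi <- keep[, 2]
    base <- rep(daily[keep], counts)
    noise <- rnorm(sum(counts), 0, rep(specs$noise_sd[vi], counts))
    fam <- rep(specs$marginal_family[vi], counts)
    value <- base + noise
    # keep lognormal variables on their positive support
    pos <- fam == "lognormal"
    value[pos] <- pmax(value[pos], base[pos] * 0.01)
    out[[d]] <- tibble::tibble(
      patient_id = rep(ids[keep[, 1]], counts),
      day = d,
      variable = rep(specs$name[vi], counts),
      value = value
    )
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$patient_id, .data$day, .data$variable)
}

latent_to_natural <- function(z, specs) {
  daily <- z
  for (j in seq_len(nrow(specs))) {
    daily[, j] <- if (specs$marginal_family[j] == "lognormal") {
      exp(specs$location[j] + specs$scale[j] * z[, j])
    } else {
      specs$location[j] + specs$scale[j] * z[, j]
    }
  }
  daily
}

missing_rate_vector <- function(missing_rate, names) {
  if (length(missing_rate) == 1 && is.null(names(missing_rate))) {
    return(rep(missing_rate, length(names)))
  }
  if (!all(names %in% names(missing_rate))) {
    abort("Named `missing_rate` must cover every variable.")
  }
  unname(missing_rate[names])
}

#' Log-normal parameters matching a target mean and SD
#'
#' Solves for the log-scale location and scale of a log-normal distribution
#' whose mean and SD in natural units equal the targets.
#'
#' @param mean,sd Target mean and SD in natural units (both positive).
#' @return Named numeric vector `c(location, scale)` on the log scale.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  c(location = log(mean) - s2 / 2, scale = sqrt(s2))
}

#' Default 11-variable ICU panel
#'
#' Variable specifications and cohort configuration emulating the day-1
#' statistical structure of a large adult ICU cohort: skewed (log-normal)
#' marginals for platelet count, WBC, glucose, BUN, creatinine, and lactate;
#' approximately normal marginals for hematocrit, bicarbonate, potassium,
#' sodium, and chloride; strong latent coupling for creatinine-BUN and
#' sodium-chloride, moderate negative bicarbonate-lactate coupling, weak
#' WBC-platelet coupling; high day-to-day persistence for creatinine, BUN,
#' and platelet count; monotone attrition to roughly 68% of the cohort on
#' day 2 and 46% on day 3; and a high missing rate for lactate, the least
#' frequently ordered test of the panel. All numeric defaults are tuned
#' emulation targets, not measured constants.
#'
#' @param n_patients Day-1 cohort size (default 5000).
#' @param seed RNG seed for the returned configuration.
#' @return A list with `specs` (11-row tibble of [variable_spec()]s) and
#'   `config` (a [cohort_config()]).
#' @export
default_icu_specs <- function(n_patients = 5000, seed = 1L) {
  ln <- function(name, mean, sd, rho, noise) {
    pars <- lognormal_params(mean, sd)
    variable_spec(name, "lognormal", pars[["location"]], pars[["scale"]],
                  temporal_rho = rho, noise_sd = noise)
  }
  no <- function(name, mean, sd, rho, noise) {
    variable_spec(name, "normal", mean, sd, temporal_rho = rho, noise_sd = noise)
  }
  specs <- dplyr::bind_rows(
    no("hematocrit", 31.9, 5.0,  0.85, 0.5),
    ln("platelet", 218.4, 112.2, 0.93, 5.0),
    ln("wbc",       12.3,   8.8, 0.65, 0.4),
    ln("glucose",  139.3,  50.5, 0.45, 5.0),
    no("hco3",      24.4,   4.6, 0.75, 0.5),
    no("potassium",  4.1,   0.5, 0.55, 0.1),
    no("sodium",   138.6,   4.4, 0.80, 0.5),
    no("chloride", 105.5,   5.7, 0.80, 0.5),
    ln("bun",       25.3,  20.9, 0.93, 1.0),
    ln("creatinine", 1.4,   1.5, 0.95, 0.05),
    ln("lactate",    2.5,   2.0, 0.50, 0.1)
  )
  R <- diag(11)
  rownames(R) <- colnames(R) <- specs$name
  set_pair <- function(R, a, b, r) {
    R[a, b] <- R[b, a] <- r
    R
  }
  R <- set_pair(R, "creatinine", "bun", 0.80)
  R <- set_pair(R, "sodium", "chloride", 0.75)
  R <- set_pair(R, "hco3", "lactate", -0.40)
  R <- set_pair(R, "wbc", "platelet", 0.15)
  miss <- setNames(rep(0.01, 11), specs$name)
  miss["lactate"] <- 0.59
  config <- cohort_config(
    n_patients = n_patients, n_days = 3, cross_correlation = R,
    attrition = c(1, 0.68, 0.46), measurements_per_day = c(1L, 4L),
    missing_rate = miss, seed = seed
  )
  list(specs = specs, config = config)
}

#' Write observations as a long-format lab CSV
#'
#' Writes the canonical `patient_id,day,variable,value` CSV, sorted by
#' (patient_id, day, variable) so identical cohorts produce byte-identical
#' files.
#'
#' @param observations Tibble of observations.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lab_csv <- function(observations, path) {
  check_columns(observations, c("patient_id", "day", "variable", "value"))
  observations |>
    dplyr::arrange(.data$patient_id, .data$day, .data$variable) |>
    readr::write_csv(path)
  invisible(path)
}
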