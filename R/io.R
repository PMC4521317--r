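# Reading and writing the long-format lab CSV and YAML configurations.

#' Read a long-format lab CSV
#'
#' Expects the exact header `patient_id,day,variable,value`. Rows with a
#' non-finite value, a missing field, or a day index below 1 are dropped and
#' counted (a message reports the counts); per-variable row counts are
#' reported as well.
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the informational messages.
#' @return Tibble of observations (`patient_id` character, `day` integer,
#'   `variable` character, `value` double).
#' @export
read_lab_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expected <- c("patient_id", "day", "variable", "value")
  if (!identical(trimws(header), expected)) {
    bad <- setdiff(expected, trimws(header))
    abort(sprintf(
      "Invalid header: expected columns %s%s.",
      paste(expected, collapse = ","),
      if (length(bad)) paste0(" (missing: ", paste(bad, collapse = ", "), ")") else ""
    ))
  }
  obs <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      day = readr::col_integer(),
      variable = readr::col_character(),
      value = readr::col_double()
    )
  )
  ok <- !is.na(obs$patient_id) & !is.na(obs$variable) &
    !is.na(obs$day) & obs$day >= 1L & is.finite(obs$value)
  n_bad <- sum(!ok)
  obs <- obs[ok, ]
  if (!quiet) {
    if (n_bad > 0) {
      inform(sprintf("Dropped %d malformed/non-finite row(s).", n_bad))
    }
    counts <- dplyr::count(obs, .data$variable)
    inform(paste0(
      "Read ", nrow(obs), " observations: ",
      paste(sprintf("%s=%d", counts$variable, counts$n), collapse = ", ")
    ))
  }
  obs
}

#' Read a cohort-simulation YAML configuration
#'
#' The YAML mirrors [cohort_config()] plus a `variables` block of
#' [variable_spec()] fields; every field except `seed` has a default (the
#' default 11-variable ICU panel). `cross_correlation` may be given as a
#' list of `[var_a, var_b, rho]` triples overriding the default coupling.
#'
#' @param path Path to the YAML file.
#' @return A list with `specs` and `config`, as from [default_icu_specs()].
#' @export
read_cohort_yaml <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("`seed` is mandatory in a cohort configuration.")
  base <- default_icu_specs(
    n_patients = y$n_patients %||% 5000,
    seed = y$seed
  )
  specs <- base$specs
  if (!is.null(y$variables)) {
    specs <- dplyr::bind_rows(purrr::map(y$variables, function(v) {
      variable_spec(
        name = v$name,
        marginal_family = v$marginal_family %||% "normal",
        location = v$location, scale = v$scale,
        temporal_rho = v$temporal_rho %||% 0.5,
        noise_sd = v$noise_sd %||% 0
      )
    }))
  }
  p <- nrow(specs)
  R <- diag(p)
  rownames(R) <- colnames(R) <- specs$name
  if (is.null(y$variables) && is.null(y$cross_correlation)) {
    R <- base$config$cross_correlation
  }
  for (entry in y$cross_correlation) {
    a <- entry[[1]]
    b <- entry[[2]]
    if (!all(c(a, b) %in% specs$name)) {
      abort(sprintf("cross_correlation names unknown variable(s): %s, %s", a, b))
    }
    R[a, b] <- R[b, a] <- as.numeric(entry[[3]])
  }
  missing_rate <- y$missing_rate %||%
    (if (is.null(y$variables)) base$config$missing_rate else 0)
  if (is.list(missing_rate)) missing_rate <- unlist(missing_rate)
  n_days <- y$n_days %||% 3
  config <- cohort_config(
    n_patients = y$n_patients %||% 5000,
    n_days = n_days,
    cross_correlation = R,
    attrition = as.numeric(y$attrition %||%
                             (if (n_days == 3) c(1, 0.68, 0.46) else rep(1, n_days))),
    measurements_per_day = as.integer(y$measurements_per_day %||% c(1L, 4L)),
    missing_rate = missing_rate,
    seed = y$seed
  )
  list(specs = specs, config = config)
}

#' Read an analysis YAML configuration
#'
#' Maps YAML fields onto [run_config()]; every field has a default equal to
#' the canonical settings.
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
read_run_yaml <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  y <- yaml::read_yaml(path)
  defaults <- run_config()
  run_config(
    n_bins = y$n_bins %||% defaults$n_bins,
    lower_pct = y$lower_pct %||% defaults$lower_pct,
    upper_pct = y$upper_pct %||% defaults$upper_pct,
    day_pairs = if (is.null(y$day_pairs)) defaults$day_pairs else
      purrr::map(y$day_pairs, as.integer),
    variable_pairs = if (is.null(y$variable_pairs)) defaults$variable_pairs else
      purrr::map(y$variable_pairs, as.character),
    pooling = y$pooling %||% defaults$pooling,
    correction = y$correction %||% defaults$correction
  )
}

#' Render a human-readable report
#'
#' Writes, into `output_dir`: `results.csv` (the tidy comparison table),
#' `daily_information.png` (per-variable total vs novel information across
#' days, dashed line at the maximum achievable entropy `log2(n_bins)`),
#' `pair_redundancy.png` (each variable pair shown asymmetrically side by
#' side), and `summary.txt` naming the most and least redundant comparisons.
#'
#' @param analysis An `icu_redundancy` object (or its tidy results tibble
#'   together with `n_bins`).
#' @param output_dir Directory to write into (created if absent).
#' @param n_bins Bin count used for the dashed maximum-entropy line;
#'   inferred from `analysis` when it is an `icu_redundancy` object.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(analysis, output_dir, n_bins = NULL) {
  if (inherits(analysis, "icu_redundancy")) {
    results <- analysis$results
    n_bins <- n_bins %||% analysis$config$n_bins
  } else {
    results <- analysis
    if (is.null(n_bins)) abort("`n_bins` must be supplied with a bare results table.")
  }
  if (nrow(results) == 0) abort("Cannot render a report from empty results.")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  csv_path <- file.path(output_dir, "results.csv")
  readr::write_csv(results, csv_path)
  files <- c(files, csv_path)

  if (any(results$comparison_type == "day_pair")) {
    p1 <- plot_daily_information(results, n_bins = n_bins)
    f1 <- file.path(output_dir, "daily_information.png")
    ggplot2::ggsave(f1, p1, width = 10, height = 6, dpi = 150)
    files <- c(files, f1)
  }
  if (any(results$comparison_type == "variable_pair")) {
    p2 <- plot_pair_redundancy(results, n_bins = n_bins)
    f2 <- file.path(output_dir, "pair_redundancy.png")
    ggplot2::ggsave(f2, p2, width = 10, height = 6, dpi = 150)
    files <- c(files, f2)
  }

  mi_rows <- results[!is.na(results$mi_bits), ]
  summary_path <- file.path(output_dir, "summary.txt")
  lines <- c(
    sprintf("Redundancy analysis summary (%d comparisons, %d bins, max entropy %.2f bits)",
            nrow(results), n_bins, log2(n_bins)),
    ""
  )
  if (nrow(mi_rows) > 0) {
    top <- mi_rows[order(-mi_rows$mi_bits), ]
    lines <- c(
      lines,
      sprintf("Most redundant comparison:  %s (I = %.3f bits, n = %d)",
              top$comparison_label[1], top$mi_bits[1], top$n_pairs[1]),
      sprintf("Least redundant comparison: %s (I = %.3f bits, n = %d)",
              top$comparison_label[nrow(top)], top$mi_bits[nrow(top)],
              top$n_pairs[nrow(top)])
    )
  }
  writeLines(lines, summary_path)
  files <- c(files, summary_path)
  invisible(files)
}
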