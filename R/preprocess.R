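# Preprocessing chain: raw observations -> daily medians -> percentile
# outlier filter -> equal-width binning. Each step takes and returns tidy
# tibbles so the chain pipes.

#' Collapse raw observations to per-patient daily medians
#'
#' One value per (patient, day, variable): the sample median of that day's
#' raw measurements (middle value for odd counts, mean of the two middle
#' values for even counts). Groups with no observations simply produce no
#' row; missing data are excluded rather than imputed.
#'
#' @param observations Data frame with columns `patient_id`, `day`,
#'   `variable`, `value` (long format, one row per raw measurement).
#' @return Tibble with columns `patient_id`, `day`, `variable`,
#'   `median_value`.
#' @export
daily_median <- function(observations) {
  check_columns(observations, c("patient_id", "day", "variable", "value"))
  observations |>
    dplyr::group_by(.data$patient_id, .data$day, .data$variable) |>
    dplyr::summarise(median_value = median(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$day, .data$variable)
}

#' Percentile-based outlier filter
#'
#' For each variable, daily values below the `lower_pct` percentile or above
#' the `upper_pct` percentile are regarded as outliers and discarded.
#' Percentiles use the linear-interpolation quantile definition
#' (`stats::quantile()` type 7), and the inequalities are strict: a value
#' exactly equal to a percentile is retained. By default percentiles are
#' pooled over all days and patients so the filter, the binning, and the
#' day-wise entropies share one per-variable value domain; `by_day = TRUE`
#' computes them per (variable, day) instead, for sensitivity analysis.
#'
#' A variable (or variable-day group) with fewer than 2 distinct values is
#' returned unchanged with a warning, since its percentiles are degenerate.
#'
#' @param daily Data frame of daily medians as returned by [daily_median()].
#' @param lower_pct,upper_pct Percentile cutoffs as fractions in `[0, 1]`,
#'   default 0.01 and 0.99 (the 1st and 99th percentiles).
#' @param by_day Compute percentiles per (variable, day) rather than pooled
#'   per variable.
#' @return A list with `retained` (tibble of surviving daily values) and
#'   `discarded` (tibble of per-variable discard counts, column
#'   `n_discarded`).
#' @export
percentile_filter <- function(daily, lower_pct = 0.01, upper_pct = 0.99,
                              by_day = FALSE) {
  check_columns(daily, c("patient_id", "day", "variable", "median_value"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 1)) {
    abort("Need 0 <= lower_pct < upper_pct <= 1.")
  }
  if (nrow(daily) == 0) {
    return(list(
      retained = tibble::as_tibble(daily),
      discarded = tibble::tibble(variable = character(), n_discarded = integer())
    ))
  }
  keys <- if (by_day) c("variable", "day") else "variable"
  flagged <- daily |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(.keep_row = {
      v <- .data$median_value
      if (dplyr::n_distinct(v) < 2) {
        warn(sprintf(
          "Variable '%s' has fewer than 2 distinct values; percentile filter skipped.",
          .data$variable[1]
        ))
        rep(TRUE, length(v))
      } else {
        q <- quantile(v, c(lower_pct, upper_pct), type = 7, names = FALSE)
        v >= q[1] & v <= q[2]
      }
    }) |>
    dplyr::ungroup()
  discarded <- flagged |>
    dplyr::filter(!.data$.keep_row) |>
    dplyr::count(.data$variable, name = "n_discarded")
  retained <- flagged |>
    dplyr::filter(.data$.keep_row) |>
    dplyr::select(-".keep_row")
  list(retained = retained, discarded = discarded)
}

#' Fit equal-width binning schemes
#'
#' Per variable (pooled over days, so that bin meanings are constant across
#' days and day-wise entropies are directly comparable): `n_bins` equal-width
#' bins spanning the minimum to the maximum retained value. With 20 bins the
#' maximum achievable entropy of the binned variable is `log2(20) = 4.32`
#' bits.
#'
#' @param retained Data frame of retained daily values (see
#'   [percentile_filter()]).
#' @param n_bins Number of equal-width bins, default 20.
#' @param by_day Fit one scheme per (variable, day) rather than pooled.
#' @return Tibble with one row per scheme: `variable` (and `day` if
#'   `by_day`), `n_bins`, `lower_edge`, `upper_edge`, `bin_width`.
#' @export
fit_binning <- function(retained, n_bins = 20, by_day = FALSE) {
  check_columns(retained, c("variable", "median_value"))
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  keys <- if (by_day) c("variable", "day") else "variable"
  schemes <- retained |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_bins = as.integer(n_bins),
      lower_edge = min(.data$median_value),
      upper_edge = max(.data$median_value),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin_width = (.data$upper_edge - .data$lower_edge) / n_bins)
  degenerate <- schemes$variable[schemes$upper_edge <= schemes$lower_edge]
  if (length(degenerate) > 0) {
    abort(sprintf(
      "Cannot fit equal-width bins: variable(s) %s have a single distinct value.",
      paste(unique(degenerate), collapse = ", ")
    ))
  }
  schemes
}

#' Map values to equal-width bin indices
#'
#' `bin = floor((value - lower_edge) / bin_width)`, clamped to `n_bins - 1`
#' so that `value == upper_edge` falls in the last bin: bins are half-open
#' `[e_k, e_{k+1})` with the final bin closed.
#'
#' @param values Numeric vector; every value must lie in
#'   `[lower_edge, upper_edge]` (guaranteed when the scheme was fit on the
#'   same retained data).
#' @param scheme One row of a [fit_binning()] result (or any list with
#'   `lower_edge`, `upper_edge`, `bin_width`, `n_bins`).
#' @return Integer vector of bin indices in `[0, n_bins - 1]`.
#' @export
discretize <- function(values, scheme) {
  lo <- scheme$lower_edge
  hi <- scheme$upper_edge
  if (any(values < lo | values > hi)) {
    abort(sprintf(
      "Values outside the binning range [%g, %g]: were filter and binning fit on different data?",
      lo, hi
    ))
  }
  pmin(as.integer(floor((values - lo) / scheme$bin_width)),
       scheme$n_bins - 1L)
}

#' Discretize retained daily values against fitted schemes
#'
#' Joins each retained daily value to its variable's (or variable-day's)
#' binning scheme and applies [discretize()].
#'
#' @param retained Tibble of retained daily values.
#' @param schemes Tibble of binning schemes from [fit_binning()].
#' @return Tibble with columns `patient_id`, `day`, `variable`, `bin_index`.
#' @export
bin_values <- function(retained, schemes) {
  keys <- intersect(c("variable", "day"), names(schemes))
  binned <- retained |>
    dplyr::inner_join(schemes, by = keys, suffix = c("", ".scheme"))
  if (nrow(binned) < nrow(retained)) {
    abort("Some retained values have no matching binning scheme.")
  }
  binned |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(bin_index = discretize(
      .data$median_value,
      list(lower_edge = .data$lower_edge[1], upper_edge = .data$upper_edge[1],
           bin_width = .data$bin_width[1], n_bins = .data$n_bins[1])
    )) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "day", "variable", "bin_index")
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
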