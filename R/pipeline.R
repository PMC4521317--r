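# Redundancy pipeline: orchestrates preprocessing and the information
# measures over the study design — per-variable daily entropies,
# consecutive-day redundancy, and same-day pairwise redundancy for
# pre-specified variable pairs. Pairs are always formed WITHIN patient and
# then pooled across patients into a single cohort-level joint distribution.

#' Analysis configuration
#'
#' Defaults reproduce the canonical settings: 20 equal-width bins, outlier
#' trimming at the 1st/99th percentiles, day pairs (1,2) and (2,3), and four
#' physiologically motivated variable pairs (creatinine-BUN,
#' bicarbonate-lactate, sodium-chloride, platelet-WBC).
#'
#' @param n_bins Number of equal-width bins per variable.
#' @param lower_pct,upper_pct Outlier percentile cutoffs (fractions).
#' @param day_pairs List of length-2 integer vectors `(d, d+1)`; each
#'   variable's day-`d` value is paired with the same patient's day-`(d+1)`
#'   value.
#' @param variable_pairs List of length-2 character vectors of variable
#'   names compared on each day.
#' @param pooling `"pooled"` (percentiles and bin edges fit once per
#'   variable across all days — the default, which makes day-wise entropies
#'   directly comparable) or `"per_day"`.
#' @param correction Entropy/MI bias correction passed to
#'   [decompose_pairs()]; plug-in (`"none"`) by default.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_bins = 20,
                       lower_pct = 0.01, upper_pct = 0.99,
                       day_pairs = list(c(1L, 2L), c(2L, 3L)),
                       variable_pairs = list(
                         c("creatinine", "bun"),
                         c("hco3", "lactate"),
                         c("sodium", "chloride"),
                         c("platelet", "wbc")
                       ),
                       pooling = c("pooled", "per_day"),
                       correction = c("none", "miller_madow")) {
  structure(
    list(
      n_bins = as.integer(n_bins),
      lower_pct = lower_pct, upper_pct = upper_pct,
      day_pairs = day_pairs, variable_pairs = variable_pairs,
      pooling = match.arg(pooling), correction = match.arg(correction)
    ),
    class = "run_config"
  )
}

result_row <- function(comparison_type, label,
                       variable_x, variable_y = NA_character_,
                       day_x, day_y = NA_integer_,
                       decomp = NULL, h_x_all = NA_real_,
                       n_available_x, n_available_y = NA_integer_) {
  tibble::tibble(
    comparison_type = comparison_type,
    comparison_label = label,
    variable_x = variable_x, variable_y = variable_y,
    day_x = as.integer(day_x), day_y = as.integer(day_y),
    h_x_bits = if (is.null(decomp)) NA_real_ else decomp$h_x,
    h_y_bits = if (is.null(decomp)) NA_real_ else decomp$h_y,
    mi_bits = if (is.null(decomp)) NA_real_ else decomp$mi,
    h_x_given_y_bits = if (is.null(decomp)) NA_real_ else decomp$h_x_given_y,
    h_y_given_x_bits = if (is.null(decomp)) NA_real_ else decomp$h_y_given_x,
    h_x_all_bits = h_x_all,
    n_available_x = as.integer(n_available_x),
    n_available_y = as.integer(n_available_y),
    n_pairs = if (is.null(decomp)) NA_integer_ else as.integer(decomp$n_pairs)
  )
}

#' Entropy of one variable on one ICU day
#'
#' Plug-in entropy over all patients with a binned value for that variable
#' on that day.
#'
#' @param binned Tibble of binned daily values (see [bin_values()]).
#' @param variable,day The variable name and 1-based ICU day.
#' @param n_bins Number of bins the values were discretized into.
#' @return One-row result tibble (`comparison_type = "day_entropy"`) with
#'   `h_x_bits` and `n_available_x`.
#' @export
day_entropy <- function(binned, variable, day, n_bins = 20) {
  bins <- binned$bin_index[binned$variable == variable & binned$day == day]
  if (length(bins) == 0) {
    abort(sprintf("No binned values for variable '%s' on day %d.", variable, day))
  }
  h <- entropy(empirical_distribution(bins, n_bins))
  result_row(
    "day_entropy", sprintf("%s: day %d", variable, day),
    variable_x = variable, day_x = day,
    decomp = tibble::tibble(h_x = h, h_y = NA_real_, mi = NA_real_,
                            h_x_given_y = NA_real_, h_y_given_x = NA_real_,
                            n_pairs = NA_integer_),
    h_x_all = h, n_available_x = length(bins)
  )
}

paired_decomposition <- function(x, y, n_bins, correction) {
  paired <- dplyr::inner_join(x, y, by = "patient_id",
                              suffix = c("_x", "_y"))
  if (nrow(paired) < 2) {
    abort(sprintf("Fewer than 2 paired patients (got %d).", nrow(paired)))
  }
  list(
    decomp = decompose_pairs(paired$bin_index_x, paired$bin_index_y,
                             n_bins, correction = correction),
    n_pairs = nrow(paired)
  )
}

#' Day-over-day redundancy of one variable
#'
#' Pairs each patient's day-`d` bin with the same patient's day-`(d+1)` bin
#' (patients missing either day are excluded from the pair set), pools the
#' pairs into a cohort-level joint distribution, and decomposes the later
#' day's information: X is day `d+1`, Y is day `d`, so `h_x_given_y_bits` is
#' the novel information in day `d+1` and `mi_bits` the redundant portion.
#' `h_x_all_bits` additionally reports the day-`(d+1)` entropy over ALL
#' patients with that day available, not just the paired subset.
#'
#' @inheritParams day_entropy
#' @param day_pair Integer vector `c(d, d + 1)` of consecutive days.
#' @param correction Bias correction, see [decompose_pairs()].
#' @return One-row result tibble (`comparison_type = "day_pair"`).
#' @export
consecutive_day_redundancy <- function(binned, variable, day_pair = c(1L, 2L),
                                       n_bins = 20,
                                       correction = c("none", "miller_madow")) {
  stopifnot(length(day_pair) == 2, day_pair[2] == day_pair[1] + 1)
  d0 <- day_pair[1]
  d1 <- day_pair[2]
  later <- binned[binned$variable == variable & binned$day == d1,
                  c("patient_id", "bin_index")]
  earlier <- binned[binned$variable == variable & binned$day == d0,
                    c("patient_id", "bin_index")]
  pd <- paired_decomposition(later, earlier, n_bins, match.arg(correction))
  h_all <- if (nrow(later) > 0) {
    entropy(empirical_distribution(later$bin_index, n_bins))
  } else {
    NA_real_
  }
  result_row(
    "day_pair", sprintf("%s: day %d | day %d", variable, d1, d0),
    variable_x = variable, variable_y = variable,
    day_x = d1, day_y = d0,
    decomp = pd$decomp, h_x_all = h_all,
    n_available_x = nrow(later), n_available_y = nrow(earlier)
  )
}

#' Same-day redundancy between two variables
#'
#' Pairs each patient's same-day bins for variables A (= X) and B (= Y) and
#' decomposes the shared information. Both conditional entropies are
#' reported, since the redundant information is symmetric but represents
#' different fractions of each variable's entropy.
#'
#' @inheritParams day_entropy
#' @param var_pair Character vector `c(A, B)` of the two variables.
#' @param correction Bias correction, see [decompose_pairs()].
#' @return One-row result tibble (`comparison_type = "variable_pair"`).
#' @export
pairwise_redundancy <- function(binned, var_pair, day, n_bins = 20,
                                correction = c("none", "miller_madow")) {
  stopifnot(length(var_pair) == 2)
  a <- binned[binned$variable == var_pair[1] & binned$day == day,
              c("patient_id", "bin_index")]
  b <- binned[binned$variable == var_pair[2] & binned$day == day,
              c("patient_id", "bin_index")]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort(sprintf("No data for pair %s-%s on day %d.",
                  var_pair[1], var_pair[2], day))
  }
  pd <- paired_decomposition(a, b, n_bins, match.arg(correction))
  h_all <- entropy(empirical_distribution(a$bin_index, n_bins))
  result_row(
    "variable_pair",
    sprintf("%s-%s: day %d", var_pair[1], var_pair[2], day),
    variable_x = var_pair[1], variable_y = var_pair[2],
    day_x = day, day_y = day,
    decomp = pd$decomp, h_x_all = h_all,
    n_available_x = nrow(a), n_available_y = nrow(b)
  )
}

#' Run the full redundancy analysis
#'
#' Executes the complete chain on raw observations: daily medians ->
#' percentile outlier filter -> equal-width binning -> (a) per-variable
#' daily entropies, (b) consecutive-day redundancy per variable, and
#' (c) same-day redundancy for the configured variable pairs. Comparisons
#' whose preconditions fail (e.g. a variable absent on a day, or fewer than
#' two paired patients) are skipped with a warning rather than aborting the
#' run.
#'
#' @param observations Tibble of raw observations (`patient_id`, `day`,
#'   `variable`, `value`).
#' @param config A [run_config()].
#' @return An object of class `icu_redundancy`: a list with `results` (tidy
#'   tibble, one row per comparison), `binning` (fitted schemes),
#'   `discarded` (per-variable outlier counts), `n_daily` (daily-median
#'   count), and `config`. Use [tidy()], [glance()], [autoplot()].
#' @export
run_full_analysis <- function(observations, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  by_day <- config$pooling == "per_day"
  daily <- daily_median(observations)
  filt <- percentile_filter(daily, config$lower_pct, config$upper_pct,
                            by_day = by_day)
  schemes <- fit_binning(filt$retained, n_bins = config$n_bins,
                         by_day = by_day)
  binned <- bin_values(filt$retained, schemes)

  grid <- dplyr::distinct(binned, .data$variable, .data$day)
  vars <- sort(unique(binned$variable))

  try_row <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      warn(sprintf("Skipping %s: %s", label, conditionMessage(e)))
      NULL
    })
  }
  entropy_rows <- purrr::pmap(grid, function(variable, day) {
    day_entropy(binned, variable, day, config$n_bins)
  })
  day_pair_rows <- purrr::map(vars, function(v) {
    purrr::map(config$day_pairs, function(dp) {
      try_row(
        sprintf("%s day pair (%d,%d)", v, dp[1], dp[2]),
        consecutive_day_redundancy(binned, v, dp, config$n_bins,
                                   correction = config$correction)
      )
    })
  })
  days <- sort(unique(binned$day))
  var_pair_rows <- purrr::map(config$variable_pairs, function(vp) {
    purrr::map(days, function(d) {
      try_row(
        sprintf("pair %s-%s day %d", vp[1], vp[2], d),
        pairwise_redundancy(binned, vp, d, config$n_bins,
                            correction = config$correction)
      )
    })
  })
  rows <- purrr::compact(c(
    entropy_rows,
    purrr::list_flatten(day_pair_rows),
    purrr::list_flatten(var_pair_rows)
  ))
  results <- dplyr::bind_rows(rows) |>
    dplyr::arrange(
      factor(.data$comparison_type,
             levels = c("day_entropy", "day_pair", "variable_pair")),
      .data$variable_x, .data$day_x
    )
  structure(
    list(
      results = results, binning = schemes, discarded = filt$discarded,
      n_daily = nrow(daily), config = config
    ),
    class = "icu_redundancy"
  )
}

#' @export
print.icu_redundancy <- function(x, ...) {
  counts <- table(x$results$comparison_type)
  cat("<icu_redundancy>\n")
  cat(sprintf(
    "  %d comparisons (%d daily entropies, %d day pairs, %d variable pairs)\n",
    nrow(x$results),
    counts["day_entropy"] %||% 0L,
    counts["day_pair"] %||% 0L,
    counts["variable_pair"] %||% 0L
  ))
  cat(sprintf("  %d bins per variable; max achievable entropy %.2f bits\n",
              x$config$n_bins, log2(x$config$n_bins)))
  invisible(x)
}

#' Tidy the results of a redundancy analysis
#'
#' @param x An `icu_redundancy` object.
#' @param ... Unused.
#' @return The tidy results tibble, one row per comparison, with entropies,
#'   mutual information, and conditional entropies in bits plus sample
#'   counts.
#' @method tidy icu_redundancy
#' @export
tidy.icu_redundancy <- function(x, ...) {
  x$results
}

#' One-row summary of a redundancy analysis
#'
#' @param x An `icu_redundancy` object.
#' @param ... Unused.
#' @return One-row tibble: number of comparisons of each kind, bin count,
#'   daily-value and discard bookkeeping.
#' @method glance icu_redundancy
#' @export
glance.icu_redundancy <- function(x, ...) {
  res <- x$results
  tibble::tibble(
    n_comparisons = nrow(res),
    n_day_entropy = sum(res$comparison_type == "day_entropy"),
    n_day_pairs = sum(res$comparison_type == "day_pair"),
    n_variable_pairs = sum(res$comparison_type == "variable_pair"),
    n_bins = x$config$n_bins,
    max_entropy_bits = log2(x$config$n_bins),
    n_daily_values = x$n_daily,
    n_discarded = sum(x$discarded$n_discarded)
  )
}
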