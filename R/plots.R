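# ggplot2 figures mirroring the structure of the standard displays: stacked
# total/novel information per ICU day, and asymmetric side-by-side pair
# redundancy. All panels carry a dashed line at log2(n_bins), the maximum
# achievable entropy.

#' Plot total and novel information per ICU day
#'
#' For each variable, day 1 shows its full entropy (all information is novel
#' on the first day); later days split the day's entropy into novel
#' (conditional entropy given the previous day) and redundant (mutual
#' information with the previous day) portions, stacked. A horizontal dashed
#' line marks the maximum achievable entropy `log2(n_bins)`.
#'
#' @param results Tidy results tibble (see [tidy.icu_redundancy()]) or an
#'   `icu_redundancy` object.
#' @param n_bins Bin count (for the dashed line); inferred when `results` is
#'   an `icu_redundancy` object.
#' @return A ggplot object.
#' @export
plot_daily_information <- function(results, n_bins = 20) {
  if (inherits(results, "icu_redundancy")) {
    n_bins <- results$config$n_bins
    results <- results$results
  }
  pairs <- results[results$comparison_type == "day_pair", ]
  day1 <- results[results$comparison_type == "day_entropy" &
                    !results$day_x %in% pairs$day_x, ]
  stacked <- dplyr::bind_rows(
    tibble::tibble(
      variable = day1$variable_x, day = day1$day_x,
      portion = "novel", bits = day1$h_x_bits
    ),
    tibble::tibble(
      variable = pairs$variable_x, day = pairs$day_x,
      portion = "novel", bits = pairs$h_x_given_y_bits
    ),
    tibble::tibble(
      variable = pairs$variable_x, day = pairs$day_x,
      portion = "redundant", bits = pairs$mi_bits
    )
  ) |>
    dplyr::mutate(portion = factor(.data$portion, c("redundant", "novel")))
  ggplot2::ggplot(
    stacked,
    ggplot2::aes(x = factor(.data$day), y = .data$bits, fill = .data$portion)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_hline(yintercept = log2(n_bins), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable)) +
    ggplot2::scale_fill_manual(values = c(novel = "#2166ac", redundant = "#b2182b")) +
    ggplot2::labs(
      x = "ICU day", y = "Information (bits)", fill = NULL,
      title = "Total and novel information in daily lab values",
      subtitle = sprintf("Dashed line: maximum achievable entropy, log2(%d) = %.2f bits",
                         n_bins, log2(n_bins))
    ) +
    ggplot2::theme_minimal()
}

#' Plot redundant information in variable pairs
#'
#' Each pair is shown asymmetrically side by side: for a pair (X, Y) and
#' day, one bar stacks H(X|Y) over I(X;Y) (total height H(X)) and the other
#' H(Y|X) over the same I(X;Y) (total height H(Y)). The redundant portion is
#' identical in both bars but represents different fractions of each
#' variable's entropy.
#'
#' @inheritParams plot_daily_information
#' @return A ggplot object.
#' @export
plot_pair_redundancy <- function(results, n_bins = 20) {
  if (inherits(results, "icu_redundancy")) {
    n_bins <- results$config$n_bins
    results <- results$results
  }
  vp <- results[results$comparison_type == "variable_pair", ]
  if (nrow(vp) == 0) abort("No variable-pair results to plot.")
  long <- dplyr::bind_rows(
    tibble::tibble(
      pair = sprintf("%s-%s", vp$variable_x, vp$variable_y), day = vp$day_x,
      side = sprintf("%s|%s", vp$variable_x, vp$variable_y),
      portion = "novel", bits = vp$h_x_given_y_bits
    ),
    tibble::tibble(
      pair = sprintf("%s-%s", vp$variable_x, vp$variable_y), day = vp$day_x,
      side = sprintf("%s|%s", vp$variable_x, vp$variable_y),
      portion = "redundant", bits = vp$mi_bits
    ),
    tibble::tibble(
      pair = sprintf("%s-%s", vp$variable_x, vp$variable_y), day = vp$day_x,
      side = sprintf("%s|%s", vp$variable_y, vp$variable_x),
      portion = "novel", bits = vp$h_y_given_x_bits
    ),
    tibble::tibble(
      pair = sprintf("%s-%s", vp$variable_x, vp$variable_y), day = vp$day_x,
      side = sprintf("%s|%s", vp$variable_y, vp$variable_x),
      portion = "redundant", bits = vp$mi_bits
    )
  ) |>
    dplyr::mutate(portion = factor(.data$portion, c("novel", "redundant")))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = interaction(.data$side, .data$day, sep = ", day "),
                 y = .data$bits, fill = .data$portion)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_hline(yintercept = log2(n_bins), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(novel = "#2166ac", redundant = "#b2182b")) +
    ggplot2::labs(
      x = NULL, y = "Information (bits)", fill = NULL,
      title = "Redundant information in lab test pairs",
      subtitle = sprintf("Dashed line: maximum achievable entropy, log2(%d) = %.2f bits",
                         n_bins, log2(n_bins))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Autoplot method for redundancy analyses
#'
#' @param object An `icu_redundancy` object.
#' @param type `"daily"` (total vs novel information per day) or `"pairs"`
#'   (asymmetric pair redundancy).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icu_redundancy
#' @export
autoplot.icu_redundancy <- function(object, type = c("daily", "pairs"), ...) {
  type <- match.arg(type)
  if (type == "daily") {
    plot_daily_information(object)
  } else {
    plot_pair_redundancy(object)
  }
}
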