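#' Forest-style plot of ranked disproportionality signals
#'
#' Reporting odds ratios with 95% CIs on a log scale, strongest signal
#' on top, with the null line at ROR = 1.
#'
#' @param ranked Output of [rank_signals()].
#' @return A ggplot object.
#' @export
plot_signals <- function(ranked) {
  ggplot2::ggplot(
    ranked,
    ggplot2::aes(x = .data$ror, y = stats::reorder(.data$drug, .data$ror))
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of multivariate logistic odds ratios
#'
#' @param forest Output of [multivariate_logistic()].
#' @return A ggplot object.
#' @export
plot_forest <- function(forest) {
  ggplot2::ggplot(
    forest,
    ggplot2::aes(x = .data$odds_ratio,
                 y = stats::reorder(.data$term, .data$odds_ratio),
                 colour = .data$significant)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Adjusted odds ratio (95% CI)", y = NULL,
                  colour = "p-adj < threshold") +
    ggplot2::theme_minimal()
}

#' Histogram of binned onset times
#'
#' @param bins Output of [bin_onsets()].
#' @return A ggplot object.
#' @export
plot_onset_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_start, y = .data$proportion)) +
    ggplot2::geom_col(width = (bins$bin_end[1] - bins$bin_start[1] + 1) * 0.9) +
    ggplot2::labs(x = "Time to onset (days, bin start)",
                  y = "Proportion of cases") +
    ggplot2::theme_minimal()
}

#' Cumulative onset curves by subgroup
#'
#' Empirical cumulative distribution of time-to-onset, one curve per
#' group — the display used to compare, e.g., fatal vs non-fatal cases.
#'
#' @param tto Tibble with an `onset_days` column.
#' @param group Optional bare column name to stratify by.
#' @return A ggplot object.
#' @export
plot_tto_ecdf <- function(tto, group = NULL) {
  g <- rlang::enquo(group)
  p <- if (rlang::quo_is_null(g)) {
    ggplot2::ggplot(tto, ggplot2::aes(x = .data$onset_days))
  } else {
    ggplot2::ggplot(tto, ggplot2::aes(x = .data$onset_days, colour = !!g))
  }
  p + ggplot2::stat_ecdf() +
    ggplot2::labs(x = "Time to onset (days)", y = "Cumulative proportion") +
    ggplot2::theme_minimal()
}

#' Annual report counts as a bar chart
#'
#' @param annual Output of [annual_counts()].
#' @return A ggplot object.
#' @export
plot_annual <- function(annual) {
  ggplot2::ggplot(tidyr::drop_na(annual, "year"),
                  ggplot2::aes(x = .data$year, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Year", y = "Reports") +
    ggplot2::theme_minimal()
}

#' Fitted Weibull density over the onset histogram
#'
#' @param object A [fit_weibull()] result.
#' @param onsets The onsets the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weibull_fit <- function(object, onsets, ...) {
  grid <- tibble(
    x = seq(1, max(onsets), length.out = 200),
    density = stats::dweibull(seq(1, max(onsets), length.out = 200),
                              shape = object$beta, scale = object$alpha)
  )
  ggplot2::ggplot(tibble(onsets = onsets), ggplot2::aes(x = .data$onsets)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "firebrick") +
    ggplot2::labs(x = "Time to onset (days)", y = "Density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
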