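# ggplot2 displays for mined patterns, test results and matching balance.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.spade_patterns <- function(object, n = 25, ...) {
  top <- object %>%
    arrange(dplyr::desc(.data$support)) %>%
    head(n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$support,
    y = stats::reorder(.data$pattern, .data$support))) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "support (proportion of sequences)", y = NULL,
                  title = sprintf("Top %d frequent condition sequences",
                                  nrow(top))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pattern_tests <- function(object, alpha = 0.05, ...) {
  df <- object %>%
    filter(.data$p_value < alpha, is.finite(.data$effect_size)) %>%
    mutate(or_signed = ifelse(.data$direction == "control",
                              1 / .data$effect_size, .data$effect_size))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$or_signed,
    y = stats::reorder(.data$pattern, .data$or_signed),
    colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "discordant-pair odds ratio (case / control)",
                  y = NULL, colour = "enriched in",
                  title = sprintf("Significant patterns (p < %s)", alpha)) +
    ggplot2::theme_minimal()
}

#' Matching balance plot
#'
#' Histogram of signed case-control age differences among matched pairs; a
#' well-behaved greedy caliper match concentrates tightly at zero.
#'
#' @param pairs Output of [greedy_match()].
#' @return A ggplot object.
#' @export
plot_matching_balance <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$age_diff_days)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "grey30") +
    ggplot2::labs(x = "control minus case age (days)", y = "pairs",
                  title = "Matched-pair age differences") +
    ggplot2::theme_minimal()
}
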