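# ggplot2 visualisations for count series and detected signals.

#' Plot topic-by-region count series
#'
#' Daily original-post counts as lines, one facet per topic, coloured by
#' region.
#'
#' @param object A `tweet_counts` tibble.
#' @param regions Optional character vector restricting the regions drawn.
#' @param total If `TRUE`, plot `count_total` instead of `count_original`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tweet_counts <- function(object, regions = NULL, total = FALSE, ...) {
  df <- object
  if (!is.null(regions)) df <- filter(df, .data$region %in% regions)
  y <- if (total) "count_total" else "count_original"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$date, y = .data[[y]],
    colour = .data$region
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$topic), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = if (total) "posts (incl. retweets/quotes)" else "original posts",
      colour = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Plot detected signals against their thresholds
#'
#' Observed counts as columns with the detection threshold overlaid, one
#' facet per topic.
#'
#' @param object A `tweet_signals` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tweet_signals <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$threshold), shape = 4, size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$topic), scales = "free") +
    ggplot2::labs(
      x = "region", y = "observed count (column) vs threshold (cross)"
    ) +
    ggplot2::theme_minimal()
}
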