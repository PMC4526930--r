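#' Plot a confusion matrix as a heat-map
#'
#' Tile plot of the 5x5 cross-tabulation with counts printed in the cells;
#' the most severe level (1) is drawn top-left, as agreement matrices are
#' conventionally printed.
#'
#' @param object a `confusion_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @examples
#' autoplot(table5_fixture())
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$engine,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_reverse(breaks = 1:nrow(object)) +
    ggplot2::scale_x_continuous(breaks = 1:ncol(object),
                                position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "reference severity", y = "engine severity") +
    ggplot2::theme_minimal()
}

#' Plot the top of a differential diagnosis list
#'
#' @param object a `triage_differential`.
#' @param top number of top-ranked entries to show.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot triage_differential
#' @export
autoplot.triage_differential <- function(object, top = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$weight,
    y = stats::reorder(.data$diagnosis_id, .data$weight)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "differential weight", y = NULL) +
    ggplot2::theme_minimal()
}
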