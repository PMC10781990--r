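#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the top high-utility itemsets
#'
#' Horizontal bar chart of the highest-utility itemsets, coloured by
#' itemset size.
#'
#' @param object A `hui_result` from [mine_hui()].
#' @param top_n Number of itemsets to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hui_result <- function(object, top_n = 20, ...) {
  df <- dplyr::slice_max(tidy(object), .data$utility, n = top_n,
                         with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$utility,
    y = stats::reorder(.data$itemset, .data$utility),
    fill = factor(.data$size)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "exact utility", y = NULL, fill = "size",
                  title = sprintf("High-utility itemsets (min_util = %s)",
                                  fmt_num(attr(object, "min_util")))) +
    ggplot2::theme_minimal()
}

#' Plot a fuzzy partition's membership functions
#'
#' Membership curves of the Low/Normal/High terms over the attribute axis,
#' with the reference-range bounds marked.
#'
#' @param object A [fuzzy_partition()].
#' @param n Number of evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fuzzy_partition <- function(object, n = 400, ...) {
  span <- object$hi - object$lo
  xs <- seq(object$lo - 0.6 * span, object$hi + 0.6 * span, length.out = n)
  df <- tidyr::pivot_longer(membership(object, xs), -"value",
                            names_to = "term", values_to = "degree")
  df$term <- factor(df$term, levels = fuzzy_terms)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$degree,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(object$lo, object$hi),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = ifelse(is.na(object$name), "value", object$name),
                  y = "membership degree", colour = NULL) +
    ggplot2::theme_minimal()
}
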