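#' Plot a space-time diagram
#'
#' Renders the diagram in the standard convention: space horizontal,
#' time running top-down, cells in state 1 black and state 0 light gray.
#'
#' @param object A `ca_diagram`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @examples
#' autoplot(ca_evolve("f7", init_single_seed(101), steps = 50))
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ca_diagram <- function(object, ...) {
  L <- unclass(object)
  df <- tibble::tibble(
    time = rep(seq_len(nrow(L)) - 1L, times = ncol(L)),
    cell = rep(seq_len(ncol(L)), each = nrow(L)),
    state = factor(as.vector(L), levels = c(0L, 1L))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$time,
                                   fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "gray85", `1` = "black"),
                               guide = "none") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "cell", y = "time",
                  title = attr(object, "rule_id")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of one measure against another with its OLS line
#'
#' @param records A measure table (e.g. [printed_measures()] or
#'   [measure_catalog()] output).
#' @param x,y Column names to plot.
#' @return A ggplot object.
#' @export
plot_measure_fit <- function(records, x = "H", y = "S") {
  fit <- linear_fit(records, y, x)
  ggplot2::ggplot(records, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = 2) +
    ggplot2::labs(
      subtitle = sprintf("%s = %.5g + %.5g * %s  (r = %.4f)",
                         y, fit$intercept, fit$slope, x, fit$r)) +
    ggplot2::theme_minimal()
}
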