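#' Plot event-type frequencies
#'
#' Bar chart of significant-junction counts per alternative-splicing
#' event category.
#'
#' @param object An `event_calls` tibble from [classify_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_calls <- function(object, ...) {
  freq <- event_frequencies(object)
  freq$category <- factor(freq$category, levels = event_categories())
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "event type", y = "significant junctions",
                  title = "Alternative-splicing event frequencies") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of events per gene
#'
#' @param calls An `event_calls` tibble.
#' @return A ggplot object: genes binned by their number of significant
#'   events.
#' @export
plot_events_per_gene <- function(calls) {
  hist <- event_count_histogram(calls)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$n_events),
                                     y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "events per gene", y = "genes",
                  title = "Genes by number of differential usage events") +
    ggplot2::theme_minimal()
}

#' Heatmap of Bliss excess over a dose matrix
#'
#' @param object A `bliss_result` from [bliss_matrix()].
#' @param ... Unused.
#' @return A ggplot object: excess effect (observed minus Bliss
#'   expectation) per combination cell; positive cells indicate synergy.
#' @export
autoplot.bliss_result <- function(object, ...) {
  grid <- tidy(object)
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(.data$dose_a),
                                     y = factor(.data$dose_b),
                                     fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "drug A dose", y = "drug B dose", fill = "excess",
                  title = "Excess over Bliss independence") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of junction usage results
#'
#' @param object A `usage_results` tibble from [usage_test()].
#' @param alpha FDR threshold highlighted (default the pipeline gate).
#' @param ... Unused.
#' @return A ggplot object of log2 usage fold change against -log10 FDR.
#' @export
autoplot.usage_results <- function(object, alpha = default_junction_alpha(),
                                   ...) {
  d <- as_tibble(unclass_results(object))
  d$significant <- d$FDR <= alpha
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$FC),
                                  y = -log10(pmax(.data$FDR, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 usage fold change", y = "-log10 FDR",
                  colour = paste0("FDR <= ", alpha)) +
    ggplot2::theme_minimal()
}
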