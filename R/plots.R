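# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.spectrum_estimate <- function(object, xlim = c(0, 60), ...) {
  df <- tidy(object)
  df <- df[df$frequency >= xlim[1] & df$frequency <= xlim[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(Amplitude~(mu*V)),
                  title = "Amplitude spectrum") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grid_search_result <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$a, y = .data$b,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ n_subbands, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste("Filter-bank weight grid:",
                                toupper(object$method)),
                  x = "a (decay exponent)", y = "b (offset)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot2::ggplot(object$per_block,
                  ggplot2::aes(x = factor(.data$block), y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = paste(toupper(object$method), "accuracy per block"),
                  x = "Block", y = "Accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.block_trend <- function(object, ...) {
  ggplot2::ggplot(object$per_block,
                  ggplot2::aes(x = .data$block, y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(title = "Accuracy over blocks", x = "Block",
                  y = "Mean accuracy") +
    ggplot2::theme_minimal()
}

#' Accuracy and ITR against data length
#'
#' @param results Tibble with columns `method`, `electrode`, `data_length`,
#'   `accuracy`, and optionally `itr` (as produced by [run_pipeline()]).
#' @param metric `"accuracy"` or `"itr"`.
#' @return A ggplot object.
#' @export
plot_data_length_sweep <- function(results, metric = c("accuracy", "itr")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$data_length,
                               y = .data[[metric]],
                               colour = .data$method,
                               linetype = .data$electrode)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "Data length (s)",
                  y = if (metric == "itr") "ITR (bits/min)" else "Accuracy") +
    ggplot2::theme_minimal()
}
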