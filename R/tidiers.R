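# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.decoding_result <- function(x, ...) x$per_block

#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(method = x$method, data_length = x$data_length,
                 accuracy = x$accuracy,
                 n_trials = nrow(x$predictions),
                 n_blocks = nrow(x$per_block))
}

#' @export
tidy.grid_search_result <- function(x, ...) x$surface

#' @export
glance.grid_search_result <- function(x, ...) {
  tibble::tibble(method = x$method, data_length = x$data_length,
                 a = x$optimum$a, b = x$optimum$b,
                 n_subbands = x$optimum$n_subbands,
                 accuracy = x$optimum$accuracy,
                 n_cells = nrow(x$surface), n_subjects = x$n_subjects)
}

#' @export
tidy.group_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$paired_tests, type = "paired_t_test",
                  comparison = .data$metric),
    dplyr::mutate(x$correlations, type = "pearson_correlation")
  ) |>
    dplyr::select(dplyr::any_of(c("type", "comparison", "mean_wet",
                                  "mean_dry", "t", "df", "r", "p_value")))
}

#' @export
glance.group_stats <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 prop_within_10pct =
                   x$difference_groups$proportion[
                     x$difference_groups$group == "within_10pct"])
}

#' @export
tidy.block_trend <- function(x, ...) x$per_block

#' @export
glance.block_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 slope_p_value = x$slope_p_value,
                 n_blocks = nrow(x$per_block))
}

#' @export
tidy.spectrum_estimate <- function(x, ...) {
  tibble::tibble(frequency = x$frequency, amplitude = x$amplitude)
}

#' @export
tidy.trca_model <- function(x, ...) {
  ch <- x$channel_names %||% paste0("ch", seq_len(nrow(x$filters)))
  tibble::tibble(
    class = rep(seq_len(x$n_classes), each = nrow(x$filters)),
    channel = rep(ch, times = x$n_classes),
    weight = as.vector(x$filters))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
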