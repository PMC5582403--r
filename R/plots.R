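#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a fitted chain
#'
#' `type = "trace"` shows the log-likelihood and each free parameter against
#' iteration with the burn-in boundary marked; `type = "marginal"` shows
#' post-burn-in marginal posterior histograms.
#'
#' @param object A `burst_fit`.
#' @param type `"trace"` or `"marginal"`.
#' @param bins Histogram bins for marginals.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burst_fit <- function(object, type = c("trace", "marginal"),
                               bins = 40, ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object$thetas) |>
    dplyr::mutate(iteration = dplyr::row_number(),
                  loglik = object$loglik)
  if (type == "trace") {
    long <- tidyr::pivot_longer(df, -"iteration",
                                names_to = "term", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = object$burn_in,
                          linetype = "dashed", colour = "red") +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL,
                    title = "Metropolis chain traces")
  } else {
    long <- df |>
      dplyr::filter(.data$iteration >= object$burn_in) |>
      dplyr::select(-"loglik") |>
      tidyr::pivot_longer(-"iteration",
                          names_to = "term", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
      ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                              colour = "white") +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior samples",
                    title = "Marginal posterior distributions")
  }
}

#' Compare snapshot data with model-predicted distributions
#'
#' Draws, for each sample time and active-TS count, the observed mRNA
#' histogram (points) over the model's predicted probabilities (lines) —
#' the standard visual check of a snapshot fit.
#'
#' @param data Snapshot table.
#' @param params A [parameter_set()] (e.g. posterior means).
#' @param model A `gene_model`.
#' @param M State-space truncation for the prediction.
#' @param bin_width mRNA bin width for display (default 10).
#' @return A ggplot object.
#' @export
plot_snapshot_fit <- function(data, params, model = two_state_model(2),
                              M = 500, bin_width = 10) {
  space <- state_space(M, model)
  data <- snapshot_data(data, model, space)
  pred <- distribution_table(params, model, space,
                             times = sort(unique(data$time_min)),
                             warn = FALSE)
  binned <- function(df, w) {
    df |>
      dplyr::mutate(bin = .data$mrna_count %/% w * w + w / 2) |>
      dplyr::group_by(.data$time_min, .data$ts_count, .data$bin)
  }
  obs <- binned(data, bin_width) |>
    dplyr::summarise(value = sum(.data$n_cells), .groups = "drop_last") |>
    dplyr::group_by(.data$time_min) |>
    dplyr::mutate(value = .data$value / sum(.data$value)) |>
    dplyr::ungroup()
  fit <- binned(pred, bin_width) |>
    dplyr::summarise(value = sum(.data$probability), .groups = "drop")
  ggplot2::ggplot(fit, ggplot2::aes(.data$bin, .data$value,
                                    colour = factor(.data$ts_count))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs) +
    ggplot2::facet_wrap(~time_min, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mRNA per cell", y = "probability mass",
                  colour = "active TS",
                  title = "Observed vs predicted snapshot distributions")
}
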