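#' Validate and aggregate a snapshot table
#'
#' Snapshot data are tidy tables with one row per observed cell state and
#' columns `time_min` (minutes relative to the stimulus; 0 is the
#' pre-stimulus sample), `ts_count` (active transcription sites),
#' `mrna_count` (mRNA molecules) and `n_cells` (how many cells showed that
#' state; per-cell tables use `n_cells = 1`). This validator checks types
#' and ranges, aggregates duplicate states, and — when a model/state space
#' is supplied — rejects observations outside them with row numbers.
#'
#' @param data Data frame with the four columns above.
#' @param model Optional `gene_model` (checks `ts_count <= n_alleles`).
#' @param space Optional [state_space()] (checks `mrna_count <= M`).
#' @return A tibble of aggregated counts, sorted by time and state.
#' @export
snapshot_data <- function(data, model = NULL, space = NULL) {
  req <- c("time_min", "ts_count", "mrna_count", "n_cells")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("snapshot data is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop(what, " in row(s) ",
           paste(utils::head(which(cond), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  for (col in req) {
    bad_row(!is.finite(data[[col]]), paste0("non-finite `", col, "`"))
  }
  for (col in c("ts_count", "mrna_count", "n_cells")) {
    bad_row(data[[col]] < 0 | data[[col]] != round(data[[col]]),
            paste0("`", col, "` must be a nonnegative integer"))
  }
  bad_row(data$time_min < 0, "`time_min` must be >= 0")
  if (!is.null(model)) {
    bad_row(data$ts_count > model$n_alleles,
            paste0("`ts_count` exceeds n_alleles = ", model$n_alleles))
  }
  if (!is.null(space)) {
    bad_row(data$mrna_count > space$M,
            paste0("`mrna_count` exceeds the truncation M = ", space$M,
                   "; raise M"))
  }
  if (!any(data$time_min == 0)) {
    stop("snapshot data must include a pre-stimulus sample at time 0.",
         call. = FALSE)
  }
  data |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$time_min, .data$ts_count, .data$mrna_count) |>
    dplyr::summarise(n_cells = sum(.data$n_cells), .groups = "drop") |>
    dplyr::filter(.data$n_cells > 0) |>
    dplyr::arrange(.data$time_min, .data$ts_count, .data$mrna_count)
}

#' Snapshot log-likelihood of a parameter set
#'
#' The probability of the observed per-time-point cell-state counts `Y^t`
#' is a product over time points of multinomial distributions with cell
#' probabilities given by the model: the `theta_U` stationary distribution
#' at `t = 0` and the `theta_S`-evolved distributions afterwards. The
#' log-likelihood is
#' `sum_t [ ln(n_t!) - sum_k ln(Y^t_k!) + sum_i Y^t_i ln P(x_i, tau_t) ]`,
#' computed with `lgamma` throughout. The multinomial coefficient does not
#' depend on `theta` (it cancels in Metropolis ratios) but is included so
#' stored likelihoods are full likelihoods, comparable across models on the
#' same data when computing information criteria.
#'
#' Observed states whose model probability falls below `floor` (default
#' `1e-300`) make the log-likelihood `-Inf`, which a Metropolis sampler
#' treats as an automatic rejection; observed states outside the state
#' space are a configuration error instead.
#'
#' @param data Snapshot table (see [snapshot_data()]).
#' @param params A [parameter_set()].
#' @param model A `gene_model`.
#' @param space A [state_space()].
#' @param floor Probability underflow floor.
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
log_likelihood <- function(data, params, model, space, floor = 1e-300) {
  data <- snapshot_data(data, model, space)
  times <- sort(unique(data$time_min))
  dists <- predict_distributions(params, model, space, times, warn = FALSE)
  ll <- 0
  for (tt in times) {
    d <- data[data$time_min == tt, ]
    P <- dists[[as.character(tt)]]$values
    pr <- P[state_index(space, d$ts_count, d$mrna_count)]
    if (any(pr < floor)) return(-Inf)
    n_t <- sum(d$n_cells)
    ll <- ll + lgamma(n_t + 1) - sum(lgamma(d$n_cells + 1)) +
      sum(d$n_cells * log(pr))
  }
  ll
}

#' Log-likelihood of the saturated model
#'
#' Upper bound on [log_likelihood()] over all parameter sets: the
#' multinomial likelihood evaluated at the empirical state frequencies of
#' each time point.
#'
#' @param data Snapshot table.
#' @return Scalar log-likelihood bound.
#' @export
saturated_log_likelihood <- function(data) {
  data <- snapshot_data(data)
  sum(vapply(split(data, data$time_min), function(d) {
    n_t <- sum(d$n_cells)
    lgamma(n_t + 1) - sum(lgamma(d$n_cells + 1)) +
      sum(d$n_cells * log(d$n_cells / n_t))
  }, numeric(1)))
}
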