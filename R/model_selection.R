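#' Bayesian information criterion
#'
#' `BIC = -2 ln(L_hat) + m ln(n)`, where `L_hat` is the maximum likelihood
#' observed during a run, `m` the number of free parameters and `n` the
#' sample size. Here `n` counts cells: each cell is one multinomial draw, so
#' the default convention sums cells across all time points.
#'
#' @param max_loglik Maximum log-likelihood.
#' @param m Free-parameter count (>= 0).
#' @param n Sample size (> 0).
#' @return The BIC score (lower is better).
#' @export
bic <- function(max_loglik, m, n) {
  if (n <= 0) stop("`n` must be positive.", call. = FALSE)
  stopifnot(m >= 0)
  -2 * max_loglik + m * log(n)
}

#' Small-sample Akaike information criterion
#'
#' The default is the standard AICc,
#' `-2 ln(L_hat) + 2m + 2m(m+1)/(n - m - 1)`. A variant with the
#' second-order term added to `-2m` instead of `+2m` circulates in some
#' write-ups; set `as_printed = TRUE` to get that form.
#'
#' @inheritParams bic
#' @param as_printed Use the `-2m` variant instead of the standard `+2m`.
#' @return The AICc score (lower is better).
#' @export
aicc <- function(max_loglik, m, n, as_printed = FALSE) {
  if (n <= m + 1) {
    stop("`n` must exceed m + 1 for the small-sample correction.",
         call. = FALSE)
  }
  sign_m <- if (as_printed) -2 else 2
  -2 * max_loglik + sign_m * m + 2 * m * (m + 1) / (n - m - 1)
}

#' Deviance information criterion of a fitted chain
#'
#' With deviance `D(theta) = -2 ln P(Y | theta)`,
#' `DIC = 2 * D_bar - D(theta_bar)`: `D_bar` is the posterior mean deviance
#' over the post-burn-in samples and `D(theta_bar)` the deviance at the
#' post-burn-in posterior mean of `theta` (one extra likelihood
#' evaluation, with the mean taken on the linear sampling scale).
#'
#' @param fit A `burst_fit`.
#' @param burn_in Override the stored burn-in index.
#' @return List with `DIC`, `D_bar`, `D_at_mean`.
#' @export
dic <- function(fit, burn_in = fit$burn_in) {
  stopifnot(inherits(fit, "burst_fit"))
  T_len <- nrow(fit$thetas)
  if (is.na(burn_in) || burn_in >= T_len) {
    stop("empty post-burn-in segment.", call. = FALSE)
  }
  seg <- burn_in:T_len
  if (any(!is.finite(fit$loglik[seg]))) {
    stop("non-finite log-likelihood in the post-burn-in segment.",
         call. = FALSE)
  }
  D_bar <- mean(-2 * fit$loglik[seg])
  theta_bar <- colMeans(fit$thetas[seg, , drop = FALSE])
  D_at_mean <- -2 * fit$loglik_fn(theta_bar)
  list(DIC = 2 * D_bar - D_at_mean, D_bar = D_bar, D_at_mean = D_at_mean)
}

#' Information criteria of a fitted model
#'
#' @param fit A `burst_fit`.
#' @param model_name Label for the ranking table.
#' @param as_printed Forwarded to [aicc()].
#' @return A one-row tibble: `model`, `m`, `n`, `max_loglik`, `BIC`, `AICc`,
#'   `DIC`, `D_bar`, `D_at_mean`.
#' @export
information_criteria <- function(fit, model_name = "model",
                                 as_printed = FALSE) {
  stopifnot(inherits(fit, "burst_fit"))
  m <- ncol(fit$thetas)
  n <- sum(fit$data$n_cells)
  ml <- max(fit$loglik)
  d <- dic(fit)
  tibble::tibble(
    model = model_name, m = m, n = n, max_loglik = ml,
    BIC = bic(ml, m, n), AICc = aicc(ml, m, n, as_printed = as_printed),
    DIC = d$DIC, D_bar = d$D_bar, D_at_mean = d$D_at_mean
  )
}

#' Rank competing parameter-stimulus models
#'
#' Stacks per-model information-criterion rows (from
#' [information_criteria()]) fitted to the *same* data, computes
#' delta-scores against the best model under each criterion, and ranks.
#' Ties are broken in favor of fewer free parameters.
#'
#' @param results A list of one-row tibbles, or a pre-bound tibble with the
#'   same columns.
#' @return A tibble in long form: `model`, `m`, `criterion`, `score`,
#'   `delta`, `rank`; the per-criterion winners are attached as the
#'   `winners` attribute (named character vector).
#' @export
compare_models <- function(results) {
  tbl <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(results)
  }
  if (nrow(tbl) < 2) {
    stop("need at least two model results to compare.", call. = FALSE)
  }
  if (length(unique(tbl$n)) != 1) {
    stop("all results must be computed on the same data (equal n).",
         call. = FALSE)
  }
  long <- tbl |>
    dplyr::select("model", "m", "BIC", "AICc", "DIC") |>
    tidyr::pivot_longer(c("BIC", "AICc", "DIC"),
                        names_to = "criterion", values_to = "score") |>
    dplyr::group_by(.data$criterion) |>
    dplyr::mutate(delta = .data$score - min(.data$score)) |>
    dplyr::arrange(.data$score, .data$m, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  winners <- long |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::select("criterion", "model") |>
    tibble::deframe()
  attr(long, "winners") <- winners
  long
}
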