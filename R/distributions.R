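#' @useDynLib snapburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
NULL

# Construct a state_dist, applying the negative-entry policy: entries in
# (-neg_tol, 0) are clipped to 0 (then optionally renormalized); anything
# more negative signals solver failure and is a hard error.
new_state_dist <- function(values, space, time_label,
                           renormalize = FALSE, neg_tol = 1e-14) {
  worst <- min(values, 0)
  if (worst < -neg_tol) {
    stop("distribution has negative entries down to ", format(worst),
         "; the solver failed.", call. = FALSE)
  }
  values[values < 0] <- 0
  mass_deficit <- 1 - sum(values)
  if (renormalize) values <- values / sum(values)
  structure(
    list(values = values, space = space, time_label = time_label,
         mass_deficit = mass_deficit),
    class = "state_dist"
  )
}

#' @export
print.state_dist <- function(x, ...) {
  cat("<state_dist> t =", format(x$time_label), "over", x$space$N,
      "states; mass deficit", format(x$mass_deficit, digits = 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.state_dist <- function(x, ...) {
  as.data.frame(tidy(x))
}

#' @rdname stationary_distribution
#' @param x A `state_dist`.
#' @param ... Unused.
#' @export
tidy.state_dist <- function(x, ...) {
  tibble::tibble(
    time = x$time_label,
    ts_count = x$space$rho1,
    mrna_count = x$space$m,
    probability = x$values
  )
}

#' Stationary distribution of the CME generator
#'
#' Solves `A p = 0`, `sum(p) = 1` for the pre-stimulus steady-state
#' distribution of cell states. Because the columns of a generator sum to
#' zero, any single row of `A` is redundant; the solver replaces the last row
#' with the normalization constraint and solves the resulting sparse system
#' by LU factorization. If that system is numerically singular, a dense SVD
#' null-space solve is used for `N <= 5000`. The residual
#' `max|A p|` must not exceed `residual_tol` after normalization; tiny
#' negative entries (magnitude < 1e-14) are clipped to zero and the vector
#' renormalized.
#'
#' For the two-state model with independent alleles the active-TS marginal
#' of this distribution is Binomial(`n_alleles`, `k1 / (k0 + k1)`) — a handy
#' closed-form check of the whole pipeline.
#'
#' @param A Sparse generator from [rate_matrix()] (columns sum to zero).
#' @param space Optional [state_space()] used to label the result; inferred
#'   dimension must match.
#' @param residual_tol Maximum allowed `max|A p|` (default `1e-10`).
#' @return A `state_dist` with `time_label = "stationary"`.
#' @export
stationary_distribution <- function(A, space = NULL, residual_tol = 1e-10) {
  n <- nrow(A)
  colsum <- Matrix::colSums(A)
  if (max(abs(colsum)) > 1e-8 * max(abs(A@x), 1)) {
    stop("`A` is not a generator: columns do not sum to zero.",
         call. = FALSE)
  }
  Tm <- as(A, "TsparseMatrix")
  keep <- Tm@i != (n - 1L)
  B <- Matrix::sparseMatrix(
    i = c(Tm@i[keep] + 1L, rep(n, n)),
    j = c(Tm@j[keep] + 1L, seq_len(n)),
    x = c(Tm@x[keep], rep(1, n)),
    dims = c(n, n)
  )
  v <- tryCatch(
    as.numeric(Matrix::solve(B, c(rep(0, n - 1L), 1))),
    error = function(e) NULL
  )
  if (is.null(v) || !all(is.finite(v))) {
    if (n > 5000) {
      stop("sparse stationary solve failed and N > 5000; the dense ",
           "null-space fallback is unavailable at this size.", call. = FALSE)
    }
    sv <- svd(as.matrix(A))
    v <- sv$v[, n]
    if (sum(v) < 0) v <- -v
  }
  v <- v / sum(v)
  resid <- max(abs(as.numeric(A %*% v)))
  if (resid > residual_tol) {
    stop("stationary solve residual ", format(resid),
         " exceeds tolerance ", format(residual_tol), ".", call. = FALSE)
  }
  if (is.null(space)) {
    space <- list(N = n, rho1 = rep(NA_integer_, n), m = rep(NA_integer_, n))
  }
  new_state_dist(v, space, "stationary", renormalize = TRUE)
}

#' Propagate a distribution through the CME
#'
#' Computes `exp(A * tau) %*% P0` — the distribution of cell states `tau`
#' minutes after the stimulus, starting from `P0` (usually the pre-stimulus
#' stationary distribution) under the post-stimulus generator. The
#' matrix-exponential action uses uniformization: with
#' `lambda = max(-diag(A))`, the series
#' `exp(-lambda t) * sum_k (lambda t)^k / k! * (I + A/lambda)^k P0`
#' is summed to a Poisson-tail truncation below `1e-15`, which preserves
#' nonnegativity and keeps the propagation error well under the `1e-12`
#' state-space-truncation budget. The dense exponential is never formed.
#'
#' The returned `mass_deficit` (`1 - sum(P)`) measures probability lost to
#' the `m > M` truncation, mirroring a finite-state-projection error check;
#' a deficit above `fsp_tol` triggers a warning advising a larger `M`.
#'
#' @param A Sparse post-stimulus generator.
#' @param P0 A `state_dist` (or bare numeric probability vector).
#' @param tau Time in minutes (>= 0).
#' @param fsp_tol Mass-deficit warning threshold (default `1e-12`).
#' @param tail_tol Poisson-tail truncation of the uniformization series.
#' @param warn Set `FALSE` to silence the mass-deficit warning (used inside
#'   tight loops where the deficit feeds into the likelihood anyway).
#' @return A `state_dist` labelled with `tau`.
#' @export
evolve <- function(A, P0, tau, fsp_tol = 1e-12, tail_tol = 1e-15,
                   warn = TRUE) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    stop("`tau` must be a single nonnegative time in minutes.", call. = FALSE)
  }
  if (inherits(P0, "state_dist")) {
    v0 <- P0$values
    space <- P0$space
  } else {
    v0 <- as.numeric(P0)
    space <- list(N = length(v0), rho1 = rep(NA_integer_, length(v0)),
                  m = rep(NA_integer_, length(v0)))
  }
  if (length(v0) != nrow(A)) stop("dimension mismatch.", call. = FALSE)
  if (tau == 0) {
    return(new_state_dist(v0, space, 0))
  }
  A <- as(A, "CsparseMatrix")
  lambda <- max(-Matrix::diag(A), 0)
  v <- cpp_expv_unif(A@i, A@p, A@x, v0, tau, lambda, tail_tol)
  out <- new_state_dist(v, space, tau)
  if (warn && out$mass_deficit > fsp_tol) {
    warning("probability-mass deficit ", format(out$mass_deficit),
            " exceeds ", format(fsp_tol),
            "; consider increasing the truncation M.", call. = FALSE)
  }
  out
}

#' Marginal distributions of a state distribution
#'
#' @param P A `state_dist` over a labelled [state_space()].
#' @return A list with `ts_marginal` (length `p`, named by TS count),
#'   `mrna_marginal` (length `M + 1`, named by mRNA count) and `joint_by_ts`
#'   (`p x (M+1)` matrix of unnormalized joint mass). All three sum to
#'   `sum(P$values)`.
#' @export
state_marginals <- function(P) {
  stopifnot(inherits(P, "state_dist"))
  sp <- P$space
  if (anyNA(sp$rho1)) stop("distribution has no labelled state space.",
                           call. = FALSE)
  joint <- matrix(P$values, nrow = sp$p, ncol = sp$M + 1L, byrow = TRUE,
                  dimnames = list(ts_count = 0:(sp$p - 1L),
                                  mrna_count = 0:sp$M))
  list(ts_marginal = rowSums(joint),
       mrna_marginal = colSums(joint),
       joint_by_ts = joint)
}

#' Model-predicted snapshot distributions at several times
#'
#' Convenience wrapper producing the distributions a snapshot experiment
#' samples from: the `theta_U` stationary distribution for `t = 0` and the
#' `theta_S`-evolved distributions for each later time, computed in one pass
#' with increasing `tau` (the propagator is reused between checkpoints).
#'
#' @param params A [parameter_set()].
#' @param model A `gene_model`.
#' @param space A [state_space()].
#' @param times Sorted nonnegative times in minutes; must start at 0.
#' @param warn Forwarded to [evolve()].
#' @return Named list of `state_dist` objects, one per time.
#' @export
predict_distributions <- function(params, model, space,
                                  times = c(0, 5, 15, 25), warn = TRUE) {
  stopifnot(inherits(params, "param_set"))
  times <- sort(unique(as.numeric(times)))
  if (times[1] != 0) {
    stop("`times` must include the pre-stimulus time 0.", call. = FALSE)
  }
  A_U <- rate_matrix(model, params$values_U, space)
  P0 <- stationary_distribution(A_U, space)
  out <- list(`0` = P0)
  post <- times[times > 0]
  if (length(post)) {
    A_S <- rate_matrix(model, params$values_S, space)
    cur <- P0
    t_prev <- 0
    for (tt in post) {
      cur <- evolve(A_S, cur, tt - t_prev, warn = warn)
      cur$time_label <- tt
      out[[as.character(tt)]] <- cur
      t_prev <- tt
    }
  }
  out
}

#' Dump predicted distributions as a tidy table
#'
#' @inheritParams predict_distributions
#' @return A tibble with columns `time_min`, `ts_count`, `mrna_count`,
#'   `probability` (one row per state and time).
#' @export
distribution_table <- function(params, model, space,
                               times = c(0, 5, 15, 25), warn = TRUE) {
  dists <- predict_distributions(params, model, space, times, warn = warn)
  purrr::map2_dfr(dists, names(dists), function(d, tm) {
    tidy(d) |>
      dplyr::mutate(time_min = as.numeric(tm), .before = 1) |>
      dplyr::select("time_min", "ts_count", "mrna_count", "probability")
  })
}
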