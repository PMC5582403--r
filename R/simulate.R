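#' Reference truth parameter sets for validation
#'
#' Two diploid two-state truth models commonly used to benchmark snapshot
#' inference. In the `k1_stim` model only the promoter activation rate jumps
#' at the stimulus; in `k1k0mu1_stim` activation, deactivation and the
#' active-state synthesis rate all change. Units: min^-1 for `k1`, `k0`,
#' `delta`; mRNA min^-1 for `mu0`, `mu1`.
#'
#' * `k1_stim`: `k1` 0.01 -> 1, `k0` = 0.1, `mu1` = 2, `mu0` = 0.01,
#'   `delta` = 0.05.
#' * `k1k0mu1_stim`: `k1` 0.01 -> 1, `k0` 1 -> 0.01, `mu1` 0.2 -> 2,
#'   `mu0` = 0.01, `delta` = 0.05.
#'
#' @return Named list of two [parameter_set()] objects (`delta` fixed).
#' @export
truth_presets <- function() {
  list(
    k1_stim = parameter_set(
      unstimulated = c(k1 = 0.01, k0 = 0.1, mu0 = 0.01, mu1 = 2,
                       delta = 0.05),
      stimulated = c(k1 = 1),
      fixed = "delta"
    ),
    k1k0mu1_stim = parameter_set(
      unstimulated = c(k1 = 0.01, k0 = 1, mu0 = 0.01, mu1 = 0.2,
                       delta = 0.05),
      stimulated = c(k1 = 1, k0 = 0.01, mu1 = 2),
      fixed = "delta"
    )
  )
}

#' Simulate snapshot data from a known truth model
#'
#' Emulates a time-resolved smFISH snapshot experiment: for each sample time
#' the exact model distribution of cell states is computed (the `theta_U`
#' stationary distribution at `t = 0`, the `theta_S`-evolved distribution
#' afterwards) and `n_cells` cells are drawn from it as one exact
#' multinomial sample. No per-cell trajectory simulation is involved; the
#' stochastic-simulation oracle is [gillespie_ssa()].
#'
#' @param params A [parameter_set()] (the truth).
#' @param model A `gene_model`.
#' @param times Sample times in minutes, starting at 0 (default
#'   `c(0, 5, 15, 25)`).
#' @param n_cells Cells per time point: a scalar (default 100) or one value
#'   per time point.
#' @param M State-space truncation.
#' @param seed Optional RNG seed; identical seeds give identical data sets.
#' @return A snapshot tibble (`time_min`, `ts_count`, `mrna_count`,
#'   `n_cells`) carrying the truth and seed as attributes `truth`, `seed`.
#' @export
simulate_snapshots <- function(params, model = two_state_model(2),
                               times = c(0, 5, 15, 25), n_cells = 100,
                               M = 500, seed = NULL) {
  stopifnot(inherits(params, "param_set"))
  times <- as.numeric(times)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing and start at 0.",
         call. = FALSE)
  }
  if (length(n_cells) == 1) n_cells <- rep(n_cells, length(times))
  stopifnot(length(n_cells) == length(times), all(n_cells >= 1))
  if (!is.null(seed)) set.seed(seed)
  space <- state_space(M, model)
  dists <- predict_distributions(params, model, space, times, warn = FALSE)
  out <- purrr::map2_dfr(seq_along(times), times, function(k, tt) {
    pr <- pmax(dists[[as.character(tt)]]$values, 0)
    draw <- as.integer(stats::rmultinom(1, n_cells[k], pr))
    obs <- which(draw > 0)
    tibble::tibble(
      time_min = tt,
      ts_count = space$rho1[obs],
      mrna_count = space$m[obs],
      n_cells = draw[obs]
    )
  })
  attr(out, "truth") <- params
  attr(out, "seed") <- seed
  out
}

#' Gillespie stochastic simulation of the reaction system
#'
#' Exact-stochastic trajectories of the untruncated reaction system,
#' independent of the master-equation solvers — the brute-force oracle used
#' to validate them. Two-state-family models run in compiled code; any
#' other `gene_model` falls back to a plain R event loop. Both paths use
#' R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param theta Named numeric vector of rates.
#' @param model A `gene_model`.
#' @param t_end Simulated time span in minutes.
#' @param n_traj Number of independent trajectories.
#' @param seed Optional RNG seed.
#' @param init_state Initial `(rho1, m)`: a length-2 vector recycled to all
#'   trajectories, or a 2-column matrix with one row per trajectory.
#' @return A tibble of end states: `ts_count`, `mrna_count` (one row per
#'   trajectory).
#' @export
gillespie_ssa <- function(theta, model = two_state_model(2), t_end,
                          n_traj = 1, seed = NULL,
                          init_state = c(0L, 0L)) {
  if (any(theta < 0)) stop("rates must be nonnegative.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(init_state)) {
    stopifnot(ncol(init_state) == 2, nrow(init_state) == n_traj)
    rho0 <- as.integer(init_state[, 1])
    m0 <- as.integer(init_state[, 2])
  } else {
    rho0 <- rep(as.integer(init_state[1]), n_traj)
    m0 <- rep(as.integer(init_state[2]), n_traj)
  }
  if (identical(model$name, "two_state")) {
    end <- cpp_ssa_two_state(theta[["k1"]], theta[["k0"]], theta[["mu0"]],
                             theta[["mu1"]], theta[["delta"]],
                             model$n_alleles, t_end, rho0, m0)
    return(tibble::tibble(ts_count = end[, 1], mrna_count = end[, 2]))
  }
  # generic (interpreted) SSA for user-defined models
  ends <- matrix(0L, n_traj, 2)
  for (tr in seq_len(n_traj)) {
    rho <- rho0[tr]; m <- m0[tr]; t <- 0
    repeat {
      a <- vapply(model$reactions,
                  function(r) r$rate(rho, m, theta), numeric(1))
      a0 <- sum(a)
      if (a0 <= 0) break
      t <- t + stats::rexp(1, a0)
      if (t > t_end) break
      k <- sample.int(length(a), 1, prob = a)
      nu <- model$reactions[[k]]$nu
      rho <- rho + nu[1]; m <- m + nu[2]
    }
    ends[tr, ] <- c(rho, m)
  }
  tibble::tibble(ts_count = ends[, 1], mrna_count = ends[, 2])
}

#' SSA sample of the post-stimulus snapshot distribution
#'
#' Simulates the full snapshot experiment by stochastic simulation alone:
#' each trajectory is first equilibrated under `theta_U` for `t_burn`
#' minutes (long relative to the slowest pre-stimulus timescale), then
#' switched to `theta_S` for `tau` minutes. The end states form an
#' empirical sample of the same distribution that
#' [predict_distributions()] computes from the master equation — with no
#' shared code path, which is what makes it an oracle.
#'
#' @param params A [parameter_set()].
#' @param model A `gene_model`.
#' @param tau Minutes after the stimulus (0 gives the pre-stimulus sample).
#' @param n_traj Number of cells to simulate.
#' @param t_burn Pre-stimulus equilibration time in minutes (default: 20
#'   times the slowest pre-stimulus relaxation time).
#' @param seed Optional RNG seed.
#' @return Tibble of `ts_count`, `mrna_count` end states.
#' @export
ssa_snapshot <- function(params, model = two_state_model(2), tau,
                         n_traj = 1e5, t_burn = NULL, seed = NULL) {
  stopifnot(inherits(params, "param_set"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_burn)) {
    th <- params$values_U
    slow <- min(th[["k1"]] + th[["k0"]], th[["delta"]])
    t_burn <- 20 / slow
  }
  pre <- gillespie_ssa(params$values_U, model, t_end = t_burn,
                       n_traj = n_traj)
  if (tau == 0) return(pre)
  gillespie_ssa(params$values_S, model, t_end = tau, n_traj = n_traj,
                init_state = as.matrix(pre))
}

#' Total-variation distance between an empirical sample and a distribution
#'
#' With `bin_width = 1` the comparison is per cell state. An empirical
#' histogram of `n` draws carries irreducible multinomial noise of order
#' `sqrt(n_bins / n)` in total variation, so comparisons against
#' finite-sample oracles are usually made on the display binning of smFISH
#' histograms (`bin_width = 20` mRNAs), which keeps the noise floor well
#' below solver-error scales of interest.
#'
#' @param sample Tibble of `ts_count`, `mrna_count` draws (e.g. from
#'   [ssa_snapshot()]).
#' @param dist A `state_dist`. Sampled states beyond the truncation are
#'   counted against the model's (near-zero) tail mass.
#' @param bin_width mRNA bin width used for the comparison histogram.
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(sample, dist, bin_width = 1) {
  stopifnot(inherits(dist, "state_dist"))
  sp <- dist$space
  inside <- sample$ts_count < sp$p & sample$mrna_count <= sp$M
  n <- nrow(sample)
  if (bin_width == 1) {
    idx <- state_index(sp, sample$ts_count[inside],
                       sample$mrna_count[inside])
    emp <- tabulate(idx, nbins = sp$N) / n
    return(0.5 * (sum(abs(emp - dist$values)) + sum(!inside) / n))
  }
  nb <- sp$M %/% bin_width + 1L
  cell <- function(ts, m) ts * nb + m %/% bin_width + 1L
  emp <- tabulate(cell(sample$ts_count[inside], sample$mrna_count[inside]),
                  nbins = sp$p * nb) / n
  mod <- as.numeric(rowsum(dist$values, cell(sp$rho1, sp$m)))
  0.5 * (sum(abs(emp - mod)) + sum(!inside) / n)
}
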