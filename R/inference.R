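#' Heaviside (box) prior on kinetic parameters
#'
#' The prior is flat inside physiological bounds and zero outside: every
#' parameter must exceed `lower` (values below it count as non-physiological,
#' effectively negative rates), and synthesis rates are capped at `mu_max`
#' mRNA per minute (estimates of maximal transcription rates fall in the
#' 12–18 range; the default uses the permissive end). The evidence `P(Y)` is
#' a constant under a flat prior and is never computed — reported
#' log-posteriors are unnormalized.
#'
#' In a two-state model the active promoter state is *defined* as the one
#' with the higher synthesis rate, so the labeling `mu1 >= mu0` is part of
#' the model's meaning, not an extra assumption; without it every posterior
#' has an exact mirror mode with the state labels swapped. `order_mu = TRUE`
#' (default) gives zero prior mass to `mu1 < mu0` (checked on both the pre-
#' and post-stimulus parameter sets during fitting).
#'
#' @param lower Lower bound applied to every free parameter (min^-1;
#'   default `1e-8`).
#' @param mu_max Upper bound on synthesis rates (mRNA min^-1; default 18).
#' @param mu_params Names of the parameters `mu_max` constrains.
#' @param order_mu Enforce the active-state labeling `mu1 >= mu0`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(lower = 1e-8, mu_max = 18,
                       mu_params = c("mu0", "mu1"), order_mu = TRUE) {
  stopifnot(lower >= 0, mu_max > lower)
  structure(list(lower = lower, mu_max = mu_max, mu_params = mu_params,
                 order_mu = isTRUE(order_mu)),
            class = "prior_spec")
}

#' Log prior density of a free-parameter vector
#'
#' @param theta_free Named numeric vector (names as in [free_names()]).
#' @param prior A [prior_spec()].
#' @return `0` if every component is inside the prior box, else `-Inf`.
#' @export
log_prior <- function(theta_free, prior = prior_spec()) {
  nm <- names(theta_free)
  if (is.null(nm)) nm <- rep("", length(theta_free))
  if (any(theta_free < prior$lower)) return(-Inf)
  is_mu <- base_param(nm) %in% prior$mu_params
  if (any(is_mu & theta_free > prior$mu_max)) return(-Inf)
  0
}

#' Default diagonal proposal covariance
#'
#' Variances follow the scales that work well for telegraph-model rates:
#' `1e-5` for switching and basal-synthesis rates (`k1`, `k0`, `mu0`) and
#' `1e-3` for the active-state synthesis rate `mu1`. Stimulus parameters
#' inherit the variance of their base parameter for both the pre- and
#' post-stimulus component.
#'
#' @param params A [parameter_set()].
#' @param variances Named per-parameter variances; unnamed parameters fall
#'   back to `1e-5`.
#' @return Diagonal covariance matrix over the free-parameter vector.
#' @export
default_sigma <- function(params,
                          variances = c(k1 = 1e-5, k0 = 1e-5,
                                        mu0 = 1e-5, mu1 = 1e-3)) {
  fn <- free_names(params)
  v <- vapply(base_param(fn), function(b) {
    if (b %in% names(variances)) variances[[b]] else 1e-5
  }, numeric(1))
  diag(v, nrow = length(v)) |> `dimnames<-`(list(fn, fn))
}

# Validated "square root" of a proposal covariance: L with L %*% t(L) = sigma.
# Positive semi-definite sigma is allowed (zero rows propose no movement).
proposal_chol <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!isSymmetric(unname(sigma), tol = 1e-10)) {
    stop("proposal covariance must be symmetric.", call. = FALSE)
  }
  e <- eigen(sigma, symmetric = TRUE)
  if (any(e$values < -1e-12 * max(abs(e$values), 1))) {
    stop("proposal covariance must be positive semi-definite.",
         call. = FALSE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = nrow(sigma))
}

#' Draw a random-walk proposal
#'
#' Adds a multivariate-normal `N(0, sigma)` perturbation to the current
#' free-parameter vector, on the linear scale (no log transform).
#'
#' @param theta_free Current free-parameter vector.
#' @param sigma Proposal covariance (PSD, matching dimension).
#' @return Proposed vector (names preserved).
#' @export
propose <- function(theta_free, sigma) {
  L <- proposal_chol(sigma)
  if (nrow(L) != length(theta_free)) {
    stop("proposal covariance dimension mismatch.", call. = FALSE)
  }
  theta_free + as.numeric(L %*% stats::rnorm(length(theta_free)))
}

# Shared Metropolis engine. log_prior_fn is evaluated first and -Inf
# short-circuits the likelihood (identical chain law, cheaper).
run_metropolis <- function(init, loglik_fn, logprior_fn, L, iters) {
  m <- length(init)
  thetas <- matrix(NA_real_, iters, m, dimnames = list(NULL, names(init)))
  loglik <- numeric(iters)
  accepted <- logical(iters)
  cur <- init
  cur_ll <- loglik_fn(cur)
  cur_lp <- logprior_fn(cur)
  if (!is.finite(cur_ll + cur_lp)) {
    stop("initial parameters have zero posterior probability; ",
         "choose a different starting point.", call. = FALSE)
  }
  for (t in seq_len(iters)) {
    prop <- cur + as.numeric(L %*% stats::rnorm(m))
    lp <- logprior_fn(prop)
    ok <- FALSE
    if (is.finite(lp)) {
      ll <- loglik_fn(prop)
      if (is.finite(ll)) {
        ok <- log(stats::runif(1)) < (ll + lp) - (cur_ll + cur_lp)
      } else {
        stats::runif(1)  # keep the RNG stream aligned across branches
      }
    } else {
      stats::runif(1)
    }
    if (ok) {
      cur <- prop
      cur_ll <- ll
      cur_lp <- lp
    }
    thetas[t, ] <- cur
    loglik[t] <- cur_ll
    accepted[t] <- ok
  }
  list(thetas = thetas, loglik = loglik, accepted = accepted)
}

#' Metropolis sampling of an arbitrary log-density
#'
#' Bare random-walk Metropolis over a user-supplied unnormalized
#' log-density. Used mainly for validating the sampler on toy targets with
#' known stationary laws; model fitting goes through [metropolis_fit()].
#'
#' @param log_post Function of a numeric vector returning the unnormalized
#'   log density (may be `-Inf`).
#' @param init Starting vector (finite log density).
#' @param sigma Proposal covariance.
#' @param iters Number of iterations.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `thetas` (iters x m), `log_post`, `accepted`.
#' @export
metropolis_sample <- function(log_post, init, sigma, iters, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- proposal_chol(sigma)
  res <- run_metropolis(init, log_post, function(x) 0, L, iters)
  list(thetas = res$thetas, log_post = res$loglik, accepted = res$accepted)
}

# Fast likelihood closure over the free-parameter vector: validates and
# indexes the data once, precomputes the generator sparsity pattern
# (make_cme_kernel), then per call refreshes only the propensity values and
# propagates. The multinomial coefficient is theta-independent and
# precomputed. Agreement with the reference path through rate_matrix() /
# stationary_distribution() / evolve() is covered by tests.
make_loglik_fn <- function(data, template, model, space, floor = 1e-300) {
  data <- snapshot_data(data, model, space)
  kern <- make_cme_kernel(model, space)
  times <- sort(unique(data$time_min))
  per_t <- lapply(times, function(tt) {
    d <- data[data$time_min == tt, ]
    list(idx = state_index(space, d$ts_count, d$mrna_count),
         y = d$n_cells)
  })
  coef <- sum(vapply(per_t, function(pt) {
    lgamma(sum(pt$y) + 1) - sum(lgamma(pt$y + 1))
  }, numeric(1)))
  post_times <- times[times > 0]
  function(theta_free) {
    params <- set_free_values(template, theta_free)
    vU <- kern$values(params$values_U)
    P <- kern$stationary(vU)
    if (is.null(P)) return(-Inf)
    dists <- vector("list", length(times))
    dists[[1]] <- P
    if (length(post_times)) {
      vS <- kern$values(params$values_S)
      cur <- P
      t_prev <- 0
      for (k in seq_along(post_times)) {
        cur <- kern$evolve(vS, cur, post_times[k] - t_prev)
        dists[[k + 1]] <- cur  # times[1] is always 0 (validated)
        t_prev <- post_times[k]
      }
    }
    ll <- coef
    for (k in seq_along(times)) {
      pr <- dists[[k]][per_t[[k]]$idx]
      if (any(pr < floor)) return(-Inf)
      ll <- ll + sum(per_t[[k]]$y * log(pr))
    }
    ll
  }
}

#' Fit a parameter-stimulus model by Metropolis MCMC
#'
#' Samples the Bayesian posterior `P(theta | Y)` of the free parameters of a
#' stochastic gene-expression model given snapshot data, using a random-walk
#' Metropolis chain: a proposal `phi ~ theta_t + N(0, sigma)` is accepted
#' with probability `min(P(phi|Y) / P(theta_t|Y), 1)` (evaluated as a
#' log-posterior difference); rejected proposals repeat the current state.
#' All randomness flows through R's RNG, so runs are bitwise-reproducible
#' given `seed`.
#'
#' Initialization (`start = "map"`, the default) draws `init_draws`
#' candidate vectors log-uniformly inside the prior box (switching rates on
#' `[1e-4, 1]`, synthesis rates on `[1e-4, mu_max]`; rate parameters
#' plausibly span decades), takes the best log-posterior among them and
#' refines it with a short Nelder-Mead climb toward the posterior mode, so
#' the chain starts where the posterior lives and the burn-in is short —
#' which matters because the fixed proposal covariance is small relative to
#' the distances a poorly started chain must travel. `start = "random"`
#' skips the refinement; `start = "template"` starts from the free values
#' of `template` (an error is raised if that start has zero posterior).
#'
#' @param data Snapshot table (see [snapshot_data()]).
#' @param template A [parameter_set()] defining which parameters are free,
#'   stimulus-affected and fixed (fixed values are taken from it).
#' @param model A `gene_model`.
#' @param M State-space truncation (maximum mRNA count).
#' @param prior A [prior_spec()].
#' @param sigma Proposal covariance; defaults to [default_sigma()].
#' @param iters Chain length `T`. Full analyses use `1e5`; reduced lengths
#'   are adequate for well-identified synthetic data.
#' @param seed RNG seed.
#' @param start `"map"` (default), `"random"` or `"template"`.
#' @param init_draws Number of random starting candidates.
#' @return A `burst_fit` object: the chain (`thetas`, `loglik`, `accepted`),
#'   `burn_in` (see [detect_burn_in()]), `acceptance_rate`, and enough
#'   context (`model`, `space`, aggregated `data`, `loglik_fn`) to compute
#'   information criteria. Methods: [tidy()], [glance()], `autoplot()`.
#' @export
metropolis_fit <- function(data, template, model = two_state_model(2),
                           M = 500, prior = prior_spec(), sigma = NULL,
                           iters = 10000, seed = 1,
                           start = c("map", "random", "template"),
                           init_draws = 100) {
  start <- match.arg(start)
  stopifnot(inherits(template, "param_set"), iters >= 2)
  set.seed(seed)
  space <- state_space(M, model)
  data <- snapshot_data(data, model, space)
  if (is.null(sigma)) sigma <- default_sigma(template)
  fn <- free_names(template)
  L <- proposal_chol(sigma)
  if (nrow(L) != length(fn)) {
    stop("proposal covariance dimension does not match the free parameters.",
         call. = FALSE)
  }
  loglik_fn <- make_loglik_fn(data, template, model, space)
  prior_fn <- function(x) {
    lp <- log_prior(stats::setNames(x, fn), prior)
    if (is.finite(lp) && prior$order_mu) {
      ps <- set_free_values(template, x)
      mu_ok <- all(c("mu0", "mu1") %in% template$parameter_names)
      if (mu_ok &&
          (ps$values_U[["mu1"]] < ps$values_U[["mu0"]] ||
           ps$values_S[["mu1"]] < ps$values_S[["mu0"]])) {
        return(-Inf)
      }
    }
    lp
  }

  if (start == "template") {
    init <- free_values(template)
  } else {
    # rates span decades, so starting candidates are drawn log-uniformly
    # inside the prior box and the best log-posterior wins
    lo <- pmax(prior$lower, 1e-4)
    hi <- ifelse(base_param(fn) %in% prior$mu_params, prior$mu_max, 1)
    best <- NULL
    best_lp <- -Inf
    for (d in seq_len(init_draws)) {
      cand <- stats::setNames(
        exp(stats::runif(length(fn), log(lo), log(hi))), fn)
      lp <- prior_fn(cand)
      if (is.finite(lp)) lp <- lp + loglik_fn(cand)
      if (is.finite(lp) && lp > best_lp) {
        best <- cand
        best_lp <- lp
      }
    }
    if (is.null(best)) {
      stop("no random initialization had positive posterior probability; ",
           "increase `init_draws` or supply a template start.",
           call. = FALSE)
    }
    init <- best
    if (start == "map") {
      obj <- function(x) {
        lp <- prior_fn(x)
        if (!is.finite(lp)) return(1e10)
        ll <- loglik_fn(x)
        if (!is.finite(ll)) return(1e10)
        -(ll + lp)
      }
      # scale-aware restarted Nelder-Mead: free parameters span orders of
      # magnitude, so each round rescales to the current iterate and a
      # fresh simplex recovers from premature collapse; iterate until the
      # climb stalls so the stored max-likelihood (used by BIC/AICc) is
      # reliably near the true optimum
      cur <- init
      cur_val <- obj(init)
      for (round in 1:6) {
        opt <- stats::optim(cur, obj, method = "Nelder-Mead",
                            control = list(
                              maxit = 500, reltol = 1e-10,
                              parscale = pmax(abs(cur), 1e-3)))
        gain <- cur_val - opt$value
        if (opt$value < cur_val) {
          cur <- opt$par
          cur_val <- opt$value
        }
        if (gain < 0.01) break
      }
      cand <- stats::setNames(cur, fn)
      if (is.finite(prior_fn(cand)) && -cur_val > best_lp) init <- cand
    }
  }

  res <- run_metropolis(init, loglik_fn, prior_fn, L, iters)
  acc <- mean(res$accepted)
  if (acc == 0) {
    stop("no proposal was accepted in ", iters,
         " iterations; try a smaller proposal covariance.", call. = FALSE)
  }
  fit <- structure(
    list(thetas = res$thetas, loglik = res$loglik,
         accepted = res$accepted, acceptance_rate = acc,
         burn_in = NA_integer_, seed = seed, sigma = as.matrix(sigma),
         prior = prior, template = template, model = model, space = space,
         data = data, loglik_fn = loglik_fn),
    class = "burst_fit"
  )
  fit$burn_in <- detect_burn_in(fit)
  post_acc <- mean(res$accepted[fit$burn_in:iters])
  if (post_acc < 0.05 || post_acc > 0.6) {
    warning("post-burn-in acceptance rate ", signif(post_acc, 3),
            " is outside [0.05, 0.6]; consider retuning sigma.",
            call. = FALSE)
  }
  fit
}

#' Detect the burn-in period of a chain
#'
#' The burn-in is the initial stretch where the log-likelihood is still
#' climbing: it ends at the first iteration whose log-likelihood reaches
#' 99.5% of the chain maximum, operationalized for negative log-likelihoods
#' as `loglik >= max(loglik) - 0.005 * |max(loglik)|`. The returned index is
#' the first retained sample (1-based); it is capped at `T/2` with a warning
#' if the rule would discard more than half the chain.
#'
#' @param x A `burst_fit` or a numeric log-likelihood trace (length >= 2;
#'   traces shorter than 100 are accepted but give a crude estimate).
#' @return Integer index of the first post-burn-in sample.
#' @export
detect_burn_in <- function(x) {
  loglik <- if (inherits(x, "burst_fit")) x$loglik else as.numeric(x)
  T_len <- length(loglik)
  stopifnot(T_len >= 2)
  L_max <- max(loglik)
  thr <- L_max - 0.005 * abs(L_max)
  idx <- which(loglik >= thr)[1]
  cap <- max(1L, T_len %/% 2L)
  if (is.na(idx) || idx > cap) {
    warning("burn-in rule would discard more than half the chain; ",
            "capping at T/2.", call. = FALSE)
    idx <- cap
  }
  as.integer(idx)
}

#' Posterior summaries of a fitted chain
#'
#' Mean, standard deviation and central 95% interval of every free
#' parameter, computed on the post-burn-in samples only.
#'
#' @param fit A `burst_fit`.
#' @param burn_in Override the stored burn-in index.
#' @return A tibble with columns `term`, `mean`, `sd`, `conf.low`,
#'   `conf.high`.
#' @export
posterior_summary <- function(fit, burn_in = fit$burn_in) {
  stopifnot(inherits(fit, "burst_fit"))
  T_len <- nrow(fit$thetas)
  if (is.na(burn_in) || burn_in >= T_len) {
    stop("empty post-burn-in segment.", call. = FALSE)
  }
  post <- fit$thetas[burn_in:T_len, , drop = FALSE]
  tibble::tibble(
    term = colnames(post),
    mean = unname(apply(post, 2, mean)),
    sd = unname(apply(post, 2, stats::sd)),
    conf.low = unname(apply(post, 2, stats::quantile, probs = 0.025,
                            names = FALSE)),
    conf.high = unname(apply(post, 2, stats::quantile, probs = 0.975,
                             names = FALSE))
  )
}

#' @rdname posterior_summary
#' @param x A `burst_fit`.
#' @param ... Unused.
#' @export
tidy.burst_fit <- function(x, ...) posterior_summary(x)

#' @rdname posterior_summary
#' @export
glance.burst_fit <- function(x, ...) {
  tibble::tibble(
    iters = nrow(x$thetas),
    m = ncol(x$thetas),
    n_cells = sum(x$data$n_cells),
    acceptance_rate = x$acceptance_rate,
    burn_in = x$burn_in,
    max_loglik = max(x$loglik)
  )
}

#' @export
print.burst_fit <- function(x, ...) {
  cat("<burst_fit> ", nrow(x$thetas), " iterations, ",
      ncol(x$thetas), " free parameters, acceptance ",
      signif(x$acceptance_rate, 3), ", burn-in ", x$burn_in, "\n", sep = "")
  print(posterior_summary(x))
  invisible(x)
}
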