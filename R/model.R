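#' Two-state promoter model of stochastic gene expression
#'
#' Builds the reaction system for a gene whose promoter switches between an
#' inactive state (basal synthesis rate `mu0`) and an active state (synthesis
#' rate `mu1`), with activation rate `k1`, deactivation rate `k0` and
#' first-order mRNA degradation `delta`. Alleles are assumed independent, so a
#' cell with `n_alleles` gene copies is described by the number of active
#' alleles `rho1` in `0..n_alleles` together with its mRNA count `m`. Rates
#' are per minute; synthesis rates are mRNA per minute.
#'
#' The four reactions and their propensities (for a cell state `(rho1, m)`):
#'
#' * activation:    `rho1 -> rho1 + 1` at rate `k1 * (n_alleles - rho1)`
#' * inactivation:  `rho1 -> rho1 - 1` at rate `k0 * rho1`
#' * synthesis:     `m -> m + 1` at rate `mu0 * (n_alleles - rho1) + mu1 * rho1`
#' * degradation:   `m -> m - 1` at rate `delta * m`
#'
#' Reactions are stored as data (stoichiometry plus a vectorized rate rule
#' over named parameters), so other promoter architectures can be expressed
#' with [gene_model()] without changing package code.
#'
#' @param n_alleles Number of independent gene copies per cell (>= 1);
#'   2 for a diploid post-mitotic cell.
#' @return A `gene_model` object with `p = n_alleles + 1` promoter states per
#'   cell and the four reactions above.
#' @examples
#' mod <- two_state_model(2)
#' mod$p
#' @export
two_state_model <- function(n_alleles = 2) {
  if (!is.numeric(n_alleles) || length(n_alleles) != 1 ||
      n_alleles < 1 || n_alleles != round(n_alleles)) {
    stop("`n_alleles` must be a single integer >= 1.", call. = FALSE)
  }
  n_alleles <- as.integer(n_alleles)
  reactions <- list(
    reaction("activation", c(1L, 0L),
             function(rho1, m, theta) theta[["k1"]] * (n_alleles - rho1)),
    reaction("inactivation", c(-1L, 0L),
             function(rho1, m, theta) theta[["k0"]] * rho1),
    reaction("synthesis", c(0L, 1L),
             function(rho1, m, theta) {
               theta[["mu0"]] * (n_alleles - rho1) + theta[["mu1"]] * rho1
             }),
    reaction("degradation", c(0L, -1L),
             function(rho1, m, theta) theta[["delta"]] * m)
  )
  gene_model(
    n_alleles = n_alleles,
    reactions = reactions,
    parameter_names = c("k1", "k0", "mu0", "mu1", "delta"),
    name = "two_state"
  )
}

#' Define a reaction of a gene-expression model
#'
#' @param name Reaction label.
#' @param nu Length-2 integer stoichiometry over `(rho1, m)`; exactly one
#'   component must change, by +/-1.
#' @param rate Vectorized function `(rho1, m, theta)` returning nonnegative
#'   propensities; `theta` is a named numeric vector.
#' @return A `gene_reaction` object.
#' @export
reaction <- function(name, nu, rate) {
  nu <- as.integer(nu)
  if (length(nu) != 2 || sum(nu != 0L) != 1L || max(abs(nu)) != 1L) {
    stop("`nu` must change exactly one of (rho1, m) by +1 or -1.",
         call. = FALSE)
  }
  stopifnot(is.function(rate))
  structure(list(name = name, nu = nu, rate = rate),
            class = "gene_reaction")
}

#' Assemble a gene-expression model from reactions
#'
#' @param n_alleles Gene copies per cell.
#' @param reactions List of [reaction()] objects.
#' @param parameter_names Ordered character vector of rate-parameter names.
#' @param name Model family label (used by fast simulation paths).
#' @return A `gene_model` object.
#' @export
gene_model <- function(n_alleles, reactions, parameter_names,
                       name = "custom") {
  stopifnot(length(reactions) >= 1,
            all(vapply(reactions, inherits, logical(1), "gene_reaction")))
  structure(
    list(n_alleles = as.integer(n_alleles),
         p = as.integer(n_alleles + 1L),
         reactions = reactions,
         parameter_names = parameter_names,
         name = name),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$name, ": ", x$n_alleles, " allele(s), ",
      x$p, " promoter states/cell, ", length(x$reactions),
      " reactions\n", sep = "")
  cat("  parameters:", paste(x$parameter_names, collapse = ", "), "\n")
  invisible(x)
}

#' Truncated cell-state space
#'
#' Enumerates all cell states `x = (rho1, m)` with `rho1` in `0..n_alleles`
#' and mRNA count `m` in `0..M`, giving `N = p * (M + 1)` states. States are
#' ordered row-major by promoter state then mRNA count, so the (1-based) R
#' index of `(rho1, m)` is `rho1 * (M + 1) + m + 1`.
#'
#' @param M Maximum mRNA count retained by the truncation (the analysis of
#'   real data typically uses `M = 500`; tests and examples use less).
#' @param model A `gene_model` (supplies `p`).
#' @return A `state_space` object with fields `M`, `p`, `N` and the state
#'   grid vectors `rho1`, `m`.
#' @examples
#' sp <- state_space(500, two_state_model(2))
#' sp$N  # 1503
#' @export
state_space <- function(M, model) {
  stopifnot(is.numeric(M), length(M) == 1, M >= 1, M == round(M),
            inherits(model, "gene_model"))
  M <- as.integer(M)
  p <- model$p
  structure(
    list(M = M, p = p, N = p * (M + 1L),
         rho1 = rep(0:(p - 1L), each = M + 1L),
         m = rep(0:M, times = p)),
    class = "state_space"
  )
}

#' Linear index of cell states
#'
#' @param space A [state_space()].
#' @param rho1,m Integer vectors of active-allele and mRNA counts.
#' @return 1-based linear indices into the state space.
#' @export
state_index <- function(space, rho1, m) {
  if (any(rho1 < 0 | rho1 >= space$p | m < 0 | m > space$M)) {
    stop("state (rho1, m) outside the state space.", call. = FALSE)
  }
  rho1 * (space$M + 1L) + m + 1L
}

#' Decode linear state indices
#'
#' @param space A [state_space()].
#' @param i 1-based linear indices.
#' @return A tibble with columns `rho1`, `m`.
#' @export
state_decode <- function(space, i) {
  stopifnot(all(i >= 1 & i <= space$N))
  tibble::tibble(rho1 = (i - 1L) %/% (space$M + 1L),
                 m = (i - 1L) %% (space$M + 1L))
}

#' Sparse state-reaction matrix (CME generator)
#'
#' Builds the sparse generator `A(theta)` of the chemical master equation
#' `dP/dt = A P` on the truncated state space: `A[j, i]` holds the propensity
#' of the reaction taking state `i` to state `j`, and each diagonal entry is
#' minus the total outflow of its state. Reactions that would leave the
#' truncation (`m > M`) are removed from both the off-diagonal and the
#' diagonal, so every column still sums to zero and the matrix remains a
#' proper (probability-conserving) generator; the truncation error is
#' instead exposed as the mass deficit of the propagated distributions.
#'
#' @param model A `gene_model`.
#' @param theta Named numeric vector covering `model$parameter_names`, all
#'   values nonnegative.
#' @param space A [state_space()].
#' @return A `dgCMatrix` of dimension `N x N` with columns summing to zero.
#' @examples
#' mod <- two_state_model(2)
#' sp <- state_space(10, mod)
#' A <- rate_matrix(mod, c(k1 = .01, k0 = .1, mu0 = .01, mu1 = 2, delta = .05), sp)
#' max(abs(Matrix::colSums(A)))
#' @export
rate_matrix <- function(model, theta, space) {
  stopifnot(inherits(model, "gene_model"), inherits(space, "state_space"))
  miss <- setdiff(model$parameter_names, names(theta))
  if (length(miss)) {
    stop("theta is missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("all rate parameters must be finite and nonnegative.", call. = FALSE)
  }
  if (space$p != model$p) {
    stop("state space and model disagree on the number of promoter states.",
         call. = FALSE)
  }
  rho1 <- space$rho1
  m <- space$m
  N <- space$N
  ii <- jj <- integer(0)
  xx <- numeric(0)
  outflow <- numeric(N)
  for (r in model$reactions) {
    a <- r$rate(rho1, m, theta)
    if (any(a < 0)) {
      stop("reaction '", r$name, "' produced a negative propensity.",
           call. = FALSE)
    }
    r2 <- rho1 + r$nu[1]
    m2 <- m + r$nu[2]
    ok <- a > 0 & r2 >= 0 & r2 < space$p & m2 >= 0 & m2 <= space$M
    if (!any(ok)) next
    src <- which(ok)
    tgt <- r2[ok] * (space$M + 1L) + m2[ok] + 1L
    ii <- c(ii, tgt)
    jj <- c(jj, src)
    xx <- c(xx, a[ok])
    outflow[src] <- outflow[src] + a[ok]
  }
  Matrix::sparseMatrix(
    i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
    x = c(xx, -outflow), dims = c(N, N)
  )
}
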