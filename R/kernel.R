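# Internal fast path for repeated likelihood evaluations (MCMC).
#
# The sparsity pattern of the generator A(theta) is fixed by the model and
# state space (propensities are positive wherever structurally possible for
# strictly positive rates, which the Heaviside prior guarantees), so it is
# computed once; per proposal only the numeric values are refreshed and
# scattered into the stored CSC layout.
#
# The stationary solve anchors the probability of state 1 = (rho1 = 0,
# m = 0) at 1 and solves the trimmed nonsingular system
# A[-1, -1] x = -A[-1, 1] (a column-diagonally-dominant M-matrix, cheap
# sparse LU with no dense normalization row). When theta puts essentially no
# stationary mass on state 1 the relative values overflow; that and any
# other numerical trouble falls back to the reference
# stationary_distribution() path.
make_cme_kernel <- function(model, space) {
  N <- space$N
  Mp1 <- space$M + 1L
  rho1 <- space$rho1
  m <- space$m
  theta_ref <- stats::setNames(rep(1, length(model$parameter_names)),
                               model$parameter_names)
  rx <- lapply(model$reactions, function(r) {
    a <- r$rate(rho1, m, theta_ref)
    r2 <- rho1 + r$nu[1]
    m2 <- m + r$nu[2]
    ok <- a > 0 & r2 >= 0 & r2 < space$p & m2 >= 0 & m2 <= space$M
    src <- which(ok)
    list(rate = r$rate, src = src, tgt = r2[ok] * Mp1 + m2[ok] + 1L)
  })
  ti <- c(unlist(lapply(rx, `[[`, "tgt"), use.names = FALSE), seq_len(N))
  tj <- c(unlist(lapply(rx, `[[`, "src"), use.names = FALSE), seq_len(N))
  # triplets are unique (distinct reactions have distinct shifts), so seeding
  # x with the triplet index recovers the triplet -> CSC position map
  Apat <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                               dims = c(N, N))
  mapA <- as.integer(Apat@x)
  sel <- which(ti != 1L & tj != 1L)
  Cpat <- Matrix::sparseMatrix(i = ti[sel] - 1L, j = tj[sel] - 1L,
                               x = seq_along(sel), dims = c(N - 1L, N - 1L))
  mapC <- as.integer(Cpat@x)
  out1 <- which(tj == 1L & ti != 1L)  # reactions leaving the anchor state
  C <- Cpat

  values <- function(theta) {
    outflow <- numeric(N)
    vals <- vector("list", length(rx))
    for (k in seq_along(rx)) {
      r <- rx[[k]]
      a <- r$rate(rho1[r$src], m[r$src], theta)
      vals[[k]] <- a
      outflow[r$src] <- outflow[r$src] + a  # src indices are unique
    }
    trip <- c(unlist(vals, use.names = FALSE), -outflow)
    list(trip = trip, lambda = max(outflow))
  }

  stationary_fallback <- function(v) {
    A <- Matrix::sparseMatrix(i = ti, j = tj, x = v$trip, dims = c(N, N))
    P <- tryCatch(stationary_distribution(A, space),
                  error = function(e) NULL)
    if (is.null(P)) NULL else P$values
  }

  list(
    values = values,
    stationary = function(v) {
      C@x <- v$trip[sel][mapC]
      b <- numeric(N - 1L)
      b[ti[out1] - 1L] <- -v$trip[out1]
      x <- tryCatch(as.numeric(Matrix::solve(C, b)),
                    error = function(e) NULL)
      if (is.null(x) || !all(is.finite(x)) || min(x) < -1e-8 ||
          !is.finite(s <- 1 + sum(x))) {
        return(stationary_fallback(v))
      }
      p <- c(1, pmax(x, 0))
      p / sum(p)
    },
    # action of expm(A * tau) for the value set `v`
    evolve = function(v, p, tau, tail_tol = 1e-12) {
      cpp_expv_unif(Apat@i, Apat@p, v$trip[mapA], p, tau, v$lambda,
                    tail_tol)
    }
  )
}
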