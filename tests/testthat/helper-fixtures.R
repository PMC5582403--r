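# Shared fixtures: everything is generated in code at test time.

theta_ref <- c(k1 = 0.01, k0 = 0.1, mu0 = 0.01, mu1 = 2, delta = 0.05)

# independent dense enumeration of the generator from the reaction rules
# (loops over states and applies the four rules one state at a time; no
# shared code with rate_matrix)
dense_generator_oracle <- function(n_alleles, M, th) {
  p <- n_alleles + 1L
  N <- p * (M + 1L)
  idx <- function(rho, m) rho * (M + 1L) + m + 1L
  A <- matrix(0, N, N)
  for (rho in 0:(p - 1L)) {
    for (m in 0:M) {
      i <- idx(rho, m)
      moves <- list(
        list(rate = th[["k1"]] * (n_alleles - rho), rho2 = rho + 1, m2 = m),
        list(rate = th[["k0"]] * rho, rho2 = rho - 1, m2 = m),
        list(rate = th[["mu0"]] * (n_alleles - rho) + th[["mu1"]] * rho,
             rho2 = rho, m2 = m + 1),
        list(rate = th[["delta"]] * m, rho2 = rho, m2 = m - 1)
      )
      for (mv in moves) {
        if (mv$rate <= 0) next
        if (mv$rho2 < 0 || mv$rho2 > n_alleles || mv$m2 < 0 || mv$m2 > M) {
          next  # leaves the truncation: dropped entirely
        }
        j <- idx(mv$rho2, mv$m2)
        A[j, i] <- A[j, i] + mv$rate
        A[i, i] <- A[i, i] - mv$rate
      }
    }
  }
  A
}

# a small snapshot table for I/O and likelihood plumbing tests
toy_snapshots <- function() {
  tibble::tibble(
    time_min = c(0, 0, 0, 5, 5),
    ts_count = c(0, 0, 1, 2, 1),
    mrna_count = c(0, 1, 3, 10, 4),
    n_cells = c(5, 3, 1, 2, 1)
  )
}
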