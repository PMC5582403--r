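mod2 <- two_state_model(2)

test_that("stationary TS marginal is Binomial(2, k1/(k0+k1))", {
  sp <- state_space(150, mod2)
  for (th in list(theta_ref,
                  c(k1 = 0.3, k0 = 0.2, mu0 = 0.05, mu1 = 1, delta = 0.1))) {
    P <- stationary_distribution(rate_matrix(mod2, th, sp), sp)
    p <- th[["k1"]] / (th[["k1"]] + th[["k0"]])
    marg <- state_marginals(P)
    expect_lt(max(abs(marg$ts_marginal - dbinom(0:2, 2, p))), 1e-8)
  }
  # the quoted closed form at k1 = 0.01, k0 = 0.1: P(one active TS)
  P <- stationary_distribution(rate_matrix(mod2, theta_ref, sp), sp)
  expect_equal(state_marginals(P)$ts_marginal[[2]],
               2 * (1 / 11) * (10 / 11), tolerance = 1e-8)
})

test_that("constitutive limit gives a Poisson mRNA marginal", {
  sp <- state_space(200, mod2)
  th <- c(k1 = 0.2, k0 = 0.3, mu0 = 1, mu1 = 1, delta = 0.1)
  P <- stationary_distribution(rate_matrix(mod2, th, sp), sp)
  pois <- dpois(0:200, 2 * 1 / 0.1)
  tv <- 0.5 * sum(abs(state_marginals(P)$mrna_marginal - pois))
  expect_lt(tv, 1e-6)
})

test_that("stationary solve is accurate and validates its input", {
  sp <- state_space(80, mod2)
  A <- rate_matrix(mod2, theta_ref, sp)
  P <- stationary_distribution(A, sp)
  expect_lt(max(abs(as.numeric(A %*% P$values))), 1e-10)
  expect_equal(sum(P$values), 1, tolerance = 1e-12)
  expect_error(stationary_distribution(A[1:10, 1:10]), "generator")
})

test_that("evolve at tau = 0 is the identity and rejects negative times", {
  sp <- state_space(60, mod2)
  A <- rate_matrix(mod2, theta_ref, sp)
  P0 <- stationary_distribution(A, sp)
  P1 <- evolve(A, P0, 0)
  expect_equal(P1$values, P0$values, tolerance = 1e-12)
  expect_error(evolve(A, P0, -1), "nonnegative")
})

test_that("truncation mass deficit is non-increasing in M", {
  ps <- truth_presets()$k1_stim
  defs <- vapply(c(50, 100, 200, 400), function(M) {
    sp <- state_space(M, mod2)
    P0 <- stationary_distribution(rate_matrix(mod2, ps$values_U, sp), sp)
    A_S <- rate_matrix(mod2, ps$values_S, sp)
    evolve(A_S, P0, 25, warn = FALSE)$mass_deficit
  }, numeric(1))
  expect_true(all(diff(defs) <= 1e-14))
})

test_that("long-time evolution converges to the post-stimulus stationary", {
  ps <- truth_presets()$k1_stim
  sp <- state_space(250, mod2)
  P0 <- stationary_distribution(rate_matrix(mod2, ps$values_U, sp), sp)
  A_S <- rate_matrix(mod2, ps$values_S, sp)
  # 50 / min(rates) with min rate mu0 = 0.01 -> tau = 5000 minutes
  Pinf <- evolve(A_S, P0, 5000, warn = FALSE)
  Pstat <- stationary_distribution(A_S, sp)
  expect_lt(0.5 * sum(abs(Pinf$values - Pstat$values)), 1e-6)
})

test_that("marginals conserve mass and resolve a point mass", {
  sp <- state_space(20, mod2)
  v <- numeric(sp$N)
  v[state_index(sp, 1, 7)] <- 1
  P <- snapburst:::new_state_dist(v, sp, 0)
  marg <- state_marginals(P)
  expect_equal(unname(marg$ts_marginal), c(0, 1, 0))
  expect_equal(unname(which(marg$mrna_marginal == 1)), 8)
  A <- rate_matrix(mod2, theta_ref, sp)
  P2 <- evolve(A, P, 2, warn = FALSE)
  m2 <- state_marginals(P2)
  expect_equal(sum(m2$ts_marginal), sum(P2$values), tolerance = 1e-12)
  expect_equal(sum(m2$mrna_marginal), sum(P2$values), tolerance = 1e-12)
  expect_equal(sum(m2$joint_by_ts), sum(P2$values), tolerance = 1e-12)
})

test_that("fast MCMC kernel agrees with the reference solvers", {
  sp <- state_space(90, mod2)
  kern <- snapburst:::make_cme_kernel(mod2, sp)
  set.seed(77)
  for (i in 1:4) {
    th <- stats::setNames(exp(stats::runif(5, log(0.01), log(1.5))),
                          mod2$parameter_names)
    v <- kern$values(th)
    A <- rate_matrix(mod2, th, sp)
    pk <- kern$stationary(v)
    pr <- stationary_distribution(A, sp)$values
    expect_lt(max(abs(pk - pr)), 1e-10)
    ek <- kern$evolve(v, pr, 7, tail_tol = 1e-15)
    er <- evolve(A, pr, 7, warn = FALSE)$values
    expect_lt(max(abs(ek - er)), 1e-12)
  }
})

test_that("distribution tables are tidy and sum to one per time", {
  ps <- truth_presets()$k1_stim
  sp <- state_space(120, mod2)
  tbl <- distribution_table(ps, mod2, sp, times = c(0, 5), warn = FALSE)
  expect_named(tbl, c("time_min", "ts_count", "mrna_count", "probability"))
  sums <- tapply(tbl$probability, tbl$time_min, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
})
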