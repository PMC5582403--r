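mod2 <- two_state_model(2)

test_that("truth presets carry the reference parameter values", {
  tp <- truth_presets()
  k1 <- tp$k1_stim
  expect_equal(unname(k1$values_U),
               c(0.01, 0.1, 0.01, 2, 0.05))
  expect_equal(k1$values_S[["k1"]], 1)
  expect_identical(k1$stimulus, "k1")
  expect_identical(k1$fixed, "delta")
  expect_identical(n_free(k1), 5L)  # 4 free + 1 extra stimulus value

  k3 <- tp$k1k0mu1_stim
  expect_equal(k3$values_U[["mu1"]], 0.2)
  expect_equal(k3$values_S[["mu1"]], 2)
  expect_equal(k3$values_U[["k0"]], 1)
  expect_equal(k3$values_S[["k0"]], 0.01)
  expect_equal(k3$values_S[["delta"]], k3$values_U[["delta"]])
  expect_identical(n_free(k3), 7L)
  # stimulus-invariant values match across parameter sets
  inv <- setdiff(k3$parameter_names, k3$stimulus)
  expect_equal(k3$values_U[inv], k3$values_S[inv])
})

test_that("snapshot simulation is an exact multinomial sample", {
  ps <- truth_presets()$k1_stim
  dat <- simulate_snapshots(ps, mod2, n_cells = 1000, M = 150, seed = 2)
  expect_equal(as.numeric(tapply(dat$n_cells, dat$time_min, sum)),
               rep(1000, 4))
  dat2 <- simulate_snapshots(ps, mod2, n_cells = 1000, M = 150, seed = 2)
  expect_identical(dat, dat2)
  dat3 <- simulate_snapshots(ps, mod2, n_cells = 1000, M = 150, seed = 3)
  expect_false(identical(dat, dat3))

  # pre-stimulus TS fractions near Binomial(2, k1/(k1+k0))
  p <- 0.01 / 0.11
  t0 <- dat[dat$time_min == 0, ]
  frac <- vapply(0:2, function(k) {
    sum(t0$n_cells[t0$ts_count == k]) / 1000
  }, numeric(1))
  expected <- dbinom(0:2, 2, p)
  expect_true(all(abs(frac - expected) <=
                    3 * sqrt(expected * (1 - expected) / 1000) + 1e-9))
})

test_that("empirical snapshot frequencies concentrate on the truth", {
  ps <- truth_presets()$k1_stim
  sp <- state_space(150, mod2)
  d15 <- predict_distributions(ps, mod2, sp, c(0, 15), warn = FALSE)[["15"]]
  for (n in c(1e3, 1e4)) {
    dat <- simulate_snapshots(ps, mod2, times = c(0, 15), n_cells = n,
                              M = 150, seed = 50 + n)
    d <- dat[dat$time_min == 15, ]
    smp <- tibble::tibble(ts_count = rep(d$ts_count, d$n_cells),
                          mrna_count = rep(d$mrna_count, d$n_cells))
    expect_lt(tv_distance(smp, d15), 3 * sqrt(sp$N / n))
  }
})

test_that("SSA with zero rates stays put and is seed-reproducible", {
  th0 <- stats::setNames(rep(0, 5), mod2$parameter_names)
  out <- gillespie_ssa(th0, mod2, t_end = 10, n_traj = 5,
                       init_state = c(1, 4))
  expect_true(all(out$ts_count == 1 & out$mrna_count == 4))
  s1 <- gillespie_ssa(theta_ref, mod2, t_end = 20, n_traj = 200, seed = 4)
  s2 <- gillespie_ssa(theta_ref, mod2, t_end = 20, n_traj = 200, seed = 4)
  expect_identical(s1, s2)
  expect_error(gillespie_ssa(c(theta_ref[-5], delta = -1), mod2, 10, 1),
               "nonnegative")
})

test_that("SSA matches the Poisson law in the constitutive limit", {
  # promoter pinned on (k0 = 0, start fully active): mRNA ~ Poisson(2 mu1/d)
  th <- c(k1 = 1, k0 = 0, mu0 = 0, mu1 = 2, delta = 0.1)
  out <- gillespie_ssa(th, mod2, t_end = 120, n_traj = 1e5, seed = 14,
                       init_state = c(2, 0))
  lam <- 2 * 2 / 0.1
  brks <- c(-Inf, 25:55, Inf)
  obs <- table(cut(out$mrna_count, brks))
  pr <- diff(ppois(c(-1, 25:55, Inf), lam))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("generic R SSA path agrees with the compiled two-state path", {
  # same reactions registered as a custom model force the interpreted path
  custom <- gene_model(
    n_alleles = 2,
    reactions = two_state_model(2)$reactions,
    parameter_names = names(theta_ref),
    name = "custom_two_state"
  )
  th <- c(k1 = 0.5, k0 = 0.5, mu0 = 0.2, mu1 = 1, delta = 0.2)
  a <- gillespie_ssa(th, custom, t_end = 30, n_traj = 2000, seed = 15)
  b <- gillespie_ssa(th, mod2, t_end = 30, n_traj = 2000, seed = 16)
  expect_lt(abs(mean(a$mrna_count) - mean(b$mrna_count)),
            4 * sd(b$mrna_count) / sqrt(2000) * sqrt(2))
  expect_lt(abs(mean(a$ts_count) - mean(b$ts_count)), 0.08)
})

test_that("CME propagation matches the SSA oracle for random rate draws", {
  set.seed(88)
  sp <- state_space(180, mod2)
  for (i in 1:3) {
    th_U <- c(k1 = exp(runif(1, log(0.01), log(0.2))),
              k0 = exp(runif(1, log(0.1), log(1))),
              mu0 = 0.01,
              mu1 = exp(runif(1, log(0.5), log(2.5))),
              delta = 0.05)
    th_S <- th_U
    th_S[["k1"]] <- exp(runif(1, log(0.3), log(1.5)))
    ps <- parameter_set(th_U, c(k1 = th_S[["k1"]]), fixed = "delta")
    dists <- predict_distributions(ps, mod2, sp, c(0, 5, 15, 25),
                                   warn = FALSE)
    for (tau in c(5, 15, 25)) {
      smp <- ssa_snapshot(ps, mod2, tau = tau, n_traj = 5e4,
                          seed = 900 + 10 * i + tau)
      expect_lt(tv_distance(smp, dists[[as.character(tau)]],
                            bin_width = 20), 0.015)
    }
  }
})
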