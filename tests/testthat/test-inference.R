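mod2 <- two_state_model(2)

test_that("Heaviside prior rejects non-physiological parameters", {
  pr <- prior_spec()
  th <- c(k1_U = 0.01, k1_S = 1, k0 = 0.1, mu0 = 0.01, mu1 = 2)
  expect_identical(log_prior(th, pr), 0)
  th2 <- th
  th2[["k0"]] <- 1e-9  # below the 1e-8 floor counts as negative
  expect_identical(log_prior(th2, pr), -Inf)
  th3 <- th
  th3[["mu1"]] <- 20  # above the maximum transcription rate
  expect_identical(log_prior(th3, pr), -Inf)
  th4 <- th
  th4[["k1_S"]] <- 25  # switching rates have no upper bound
  expect_identical(log_prior(th4, pr), 0)
  expect_error(prior_spec(lower = 1, mu_max = 0.5))
})

test_that("default proposal covariance follows the documented scales", {
  ps <- truth_presets()$k1_stim
  S <- default_sigma(ps)
  expect_identical(colnames(S), c("k1_U", "k1_S", "k0", "mu0", "mu1"))
  expect_equal(unname(diag(S)), c(1e-5, 1e-5, 1e-5, 1e-5, 1e-3))
})

test_that("proposals are N(0, sigma) perturbations on the linear scale", {
  th <- c(a = 1, b = 2)
  expect_equal(propose(th, diag(0, 2)), th)
  expect_error(propose(th, matrix(c(1, 2, 0, 1), 2)), "symmetric")
  neg <- matrix(c(1, 0, 0, -1), 2)
  expect_error(propose(th, neg), "semi-definite")

  S <- diag(c(1e-5, 1e-3))
  set.seed(1)
  draws <- t(replicate(2e4, propose(c(0, 0), S)))
  expect_equal(apply(draws, 2, sd), sqrt(diag(S)), tolerance = 0.05)
  expect_lt(abs(cor(draws)[1, 2]), 0.03)
})

test_that("sampler reproduces known stationary laws on toy targets", {
  # flat density on the unit box: marginal must be uniform
  logp <- function(x) if (x >= 0 && x <= 1) 0 else -Inf
  res <- metropolis_sample(logp, init = 0.5, sigma = matrix(0.09),
                           iters = 1e5, seed = 42)
  ks <- suppressWarnings(stats::ks.test(res$thetas[, 1], "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  # two flat levels with masses (q, 1-q): occupancy matches q
  q <- 0.3
  logp2 <- function(x) {
    if (x >= 0 && x < 1) log(q) else if (x >= 1 && x < 2) log(1 - q)
    else -Inf
  }
  res2 <- metropolis_sample(logp2, init = 0.5, sigma = matrix(2.25),
                            iters = 1e5, seed = 43)
  occ <- mean(res2$thetas[, 1] < 1)
  expect_lt(abs(occ - q), 0.02)  # ~3 correlated-sample standard errors
})

test_that("burn-in detection applies the 99.5% log-likelihood rule", {
  expect_identical(detect_burn_in(rep(-50, 200)), 1L)
  trace <- c(-200, -150, -101, -100.4, -100.1, rep(-100, 95))
  # threshold = -100 - 0.005 * 100 = -100.5; first index reaching it is 4
  expect_identical(detect_burn_in(trace), 4L)
  # monotone traces stay above the band once entered
  mono <- c(seq(-300, -100, length.out = 50), rep(-100, 150))
  b <- detect_burn_in(mono)
  expect_true(all(mono[b:length(mono)] >= -100 - 0.5))
  expect_true(all(mono[seq_len(b - 1)] < -100 - 0.5))
  # rule reaching past T/2 is capped with a warning
  late <- c(rep(-1000, 150), rep(-100, 50))
  expect_warning(bi <- detect_burn_in(late), "half")
  expect_identical(bi, 100L)
})

test_that("posterior summaries recover a known sampling distribution", {
  set.seed(7)
  fake <- structure(
    list(thetas = matrix(rnorm(2e4, 5, 1), ncol = 1,
                         dimnames = list(NULL, "x")),
         loglik = rep(-1, 2e4), accepted = rep(TRUE, 2e4),
         burn_in = 1L, data = tibble::tibble(n_cells = 10)),
    class = "burst_fit"
  )
  s <- posterior_summary(fake)
  expect_equal(s$mean, 5, tolerance = 3 / sqrt(2e4) * 3)
  expect_equal(s$sd, 1, tolerance = 0.05)
  expect_lt(s$conf.low, 5)
  expect_gt(s$conf.high, 5)
  degen <- fake
  degen$thetas[] <- 2
  sd0 <- posterior_summary(degen)
  expect_equal(sd0$sd, 0)
  expect_equal(sd0$conf.low, sd0$conf.high)
  degen$burn_in <- NA_integer_
  expect_error(posterior_summary(degen), "burn-in")
})

test_that("same seed gives bitwise-identical chains", {
  ps <- truth_presets()$k1_stim
  dat <- simulate_snapshots(ps, mod2, times = c(0, 5), n_cells = 50,
                            M = 60, seed = 12)
  f1 <- suppressWarnings(metropolis_fit(dat, ps, mod2, M = 60, iters = 300,
                                        seed = 9, start = "template"))
  f2 <- suppressWarnings(metropolis_fit(dat, ps, mod2, M = 60, iters = 300,
                                        seed = 9, start = "template"))
  expect_identical(f1$thetas, f2$thetas)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$accepted, f2$accepted)
  f3 <- suppressWarnings(metropolis_fit(dat, ps, mod2, M = 60, iters = 300,
                                        seed = 10, start = "template"))
  expect_false(identical(f1$thetas, f3$thetas))
})

test_that("chains reject starts with zero posterior and record diagnostics", {
  ps <- truth_presets()$k1_stim
  dat <- simulate_snapshots(ps, mod2, times = c(0, 5), n_cells = 50,
                            M = 60, seed = 12)
  bad <- set_free_values(ps, c(1e-9, 1, 0.1, 0.01, 2))
  expect_error(
    metropolis_fit(dat, bad, mod2, M = 60, iters = 100, start = "template"),
    "starting point")
  fit <- suppressWarnings(metropolis_fit(dat, ps, mod2, M = 60, iters = 400,
                                         seed = 2, start = "template"))
  expect_gt(fit$acceptance_rate, 0)
  expect_lt(fit$acceptance_rate, 1)
  expect_lt(fit$burn_in, 400)
  expect_true(all(is.finite(fit$loglik)))
  g <- glance(fit)
  expect_identical(g$iters, 400L)
  expect_equal(g$n_cells, 100)
  expect_identical(g$m, 5L)
})

test_that("replica chains agree and intervals shrink with sample size", {
  ps <- truth_presets()$k1_stim
  dat100 <- simulate_snapshots(ps, mod2, n_cells = 100, M = 100, seed = 31)
  fits <- lapply(c(61, 62, 63), function(s) {
    suppressWarnings(metropolis_fit(dat100, ps, mod2, M = 100, iters = 2000,
                                    seed = s))
  })
  sums <- lapply(fits, posterior_summary)
  for (term in sums[[1]]$term) {
    lo <- vapply(sums, function(s) s$conf.low[s$term == term], numeric(1))
    hi <- vapply(sums, function(s) s$conf.high[s$term == term], numeric(1))
    expect_lt(max(lo), min(hi))  # pairwise-overlapping 95% intervals
  }

  dat30 <- simulate_snapshots(ps, mod2, n_cells = 30, M = 100, seed = 32)
  dat300 <- simulate_snapshots(ps, mod2, n_cells = 300, M = 100, seed = 32)
  w <- vapply(list(dat30, dat300), function(d) {
    s <- posterior_summary(suppressWarnings(
      metropolis_fit(d, ps, mod2, M = 100, iters = 2000, seed = 64)))
    stats::median(s$conf.high - s$conf.low)
  }, numeric(1))
  expect_gte(w[1], w[2])
})
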