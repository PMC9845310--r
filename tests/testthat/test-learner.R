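test_that("MH acceptance rule: identity, downhill, out-of-support, uphill", {
  m <- energy_model(beta = 20)
  cfg <- learner_config()
  # identity proposal always returns the current state
  expect_identical(mh_step(m, 0, 5, cfg, proposal = 5), 5)
  # downhill proposals are always accepted
  expect_identical(mh_step(m, 0, 5, cfg, proposal = 0.1), 0.1)
  # proposals outside the support are rejected (chain stays)
  expect_identical(mh_step(m, 0, 5, cfg, proposal = 95), 5)
  # strongly uphill proposals are (almost surely) rejected at high beta
  set.seed(42)
  stays <- vapply(1:500, function(i) mh_step(m, 0, 0, cfg, proposal = 10),
                  numeric(1))
  expect_true(all(stays == 0))
  expect_error(mh_step(m, 0, 200, cfg), "outside the support")
})

test_that("discretized chain satisfies detailed balance wrt the equilibrium", {
  m <- energy_model(beta = 1.5, bias = 1)
  states <- seq(-10, 10, length.out = 21)
  E <- evaluate_energy(m, states, theta = 0)
  peq <- exp(-m$beta * E) / sum(exp(-m$beta * E))
  # discretized symmetric Gaussian proposal (unproposed mass stays put, as
  # out-of-support rejections do in mh_step) + Metropolis acceptance
  q <- stats::dnorm(outer(states, states, "-"), sd = 4) * (states[2] - states[1])
  T <- q * pmin(1, exp(-m$beta * (matrix(E, 21, 21, byrow = TRUE) -
                                    matrix(E, 21, 21))))
  diag(T) <- 0
  diag(T) <- 1 - rowSums(T)
  flux <- peq * T          # flux[i, j] = p(i) T(i -> j)
  expect_lt(max(abs(flux - t(flux))), 1e-10)
})

test_that("MH chain at fixed rotation converges to the Boltzmann equilibrium", {
  m <- energy_model(beta = 1)
  cfg <- learner_config()
  set.seed(7)
  n <- 2e5
  x <- sample_equilibrium(m, 0, 1)
  xs <- numeric(n)
  for (i in seq_len(n)) {
    x <- mh_step(m, 0, x, cfg)
    xs[i] <- x
  }
  ks <- oracle_ks(xs, oracle_cdf_fun(beta = 1))
  expect_lt(ks, 0.01)
})

test_that("simulated runs are reproducible and protocol-aligned", {
  m <- energy_model(beta = 1, bias = 2)
  p <- build_protocol(n_cycles = 3, baseline_length = 20)
  t1 <- simulate_run(m, p, learner_config(), seed = 5)
  t2 <- simulate_run(m, p, learner_config(), seed = 5)
  expect_identical(t1$response_deg, t2$response_deg)
  expect_equal(nrow(t1), 20 + 3 * 66)
  expect_identical(t1$theta_deg, p$angles)
  expect_true(all(t1$response_deg >= -90 & t1$response_deg <= 90))
  # stationary all-zero protocol with a concentrated equilibrium: the
  # recorded responses stay near the biased target
  mz <- energy_model(beta = 10, bias = 2)
  pz <- build_protocol(theta_peak = 0, n_cycles = 5, baseline_length = 0)
  tz <- simulate_run(mz, pz, learner_config(proposal_scale = 5,
                                            steps_per_trial = 100),
                     seed = 6)
  expect_lt(abs(mean(tz$response_deg) - mz$bias), 2)
})

test_that("washout plateaus re-equilibrate under the default learner", {
  m <- energy_model(beta = 1)
  p <- build_protocol(n_cycles = 625)     # 16 plateau trials/cycle -> 10,000
  td <- simulate_run(m, p, learner_config(), seed = 9)
  pl <- fluctlearn:::plateau_responses(td, p)
  expect_length(pl, 10000L)
  ks <- oracle_ks(pl, oracle_cdf_fun(beta = 1))
  expect_lt(ks, 0.05)
})
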