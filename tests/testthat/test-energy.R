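test_that("exponential-quadratic energy evaluates to its closed form", {
  m <- energy_model(beta = 1)
  expect_identical(evaluate_energy(m, 0, 0), 0)
  expect_lt(abs(evaluate_energy(m, 90, 0) - 1), 1e-12)
  expect_equal(evaluate_energy(m, 9, 10), 1 - exp(-1), tolerance = 1e-12)
  # symmetric about theta + b, exactly
  mb <- energy_model(beta = 1, bias = 4)
  for (d in c(0.5, 1, 7, 30))
    expect_identical(evaluate_energy(mb, 10 + 4 + d, 10),
                     evaluate_energy(mb, 10 + 4 - d, 10))
})

test_that("mexican-hat control energy peaks at the target and dips at sigma", {
  m <- energy_model("mexican_hat", beta = 1, sigma = 4)
  expect_identical(evaluate_energy(m, 0, 0), 1)
  expect_equal(evaluate_energy(m, 4, 0), 0, tolerance = 1e-12)   # zero at u = sigma
  # the worst (highest) energy is at the target
  xs <- seq(-20, 20, by = 0.1)
  expect_equal(xs[which.max(evaluate_energy(m, xs, 0))], 0)
})

test_that("model construction rejects invalid parameters", {
  expect_error(energy_model(beta = 0), "beta")
  expect_error(energy_model(beta = -1), "beta")
  expect_error(energy_model(support = c(90, -90)), "support")
  expect_error(energy_model("mexican_hat", sigma = NULL), "sigma")
  m <- energy_model()
  expect_error(evaluate_energy(m, NA, 0), "finite")
  expect_error(evaluate_energy(m, 0, Inf), "finite")
})

test_that("free energy matches independent quadrature oracle", {
  for (beta in c(0.5, 1, 2)) for (theta in c(-30, 0, 10)) {
    m <- energy_model(beta = beta)
    expect_equal(free_energy(m, theta),
                 oracle_free_energy(beta, theta), tolerance = 1e-8)
  }
  # the documented reference value at beta = 1, theta = 0
  expect_equal(free_energy(energy_model(beta = 1), 0), -4.2074,
               tolerance = 1e-4)
})

test_that("free energy is translation invariant", {
  m <- energy_model(beta = 1)
  expect_lt(abs(free_energy(m, 0) - free_energy(m, 10)), 1e-6)
  # joint translation of theta and support
  m2 <- energy_model(beta = 1.3, support = c(-90, 90))
  m3 <- energy_model(beta = 1.3, support = c(-90, 90) + 25)
  expect_lt(abs(free_energy(m2, 5) - free_energy(m3, 30)), 1e-6)
})

test_that("equilibrium density normalizes and obeys the Boltzmann ratio", {
  for (beta in c(0.5, 1, 2)) for (b in c(-5, 0, 5)) for (theta in c(-30, 0, 30)) {
    m <- energy_model(beta = beta, bias = b)
    total <- stats::integrate(function(x) equilibrium_pdf(m, theta, x),
                              -90, 90, subdivisions = 500L,
                              rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  m <- energy_model(beta = 1, bias = 3)
  xs <- seq(-90, 90, by = 0.05)
  expect_equal(xs[which.max(equilibrium_pdf(m, 20, xs))], 23)
  # density ratio between the target and a far in-support point is
  # exp(beta * dE)
  r <- equilibrium_pdf(m, 0, 3) / equilibrium_pdf(m, 0, 3 - 90)
  expect_equal(r, exp(1 * (1 - exp(-8100))), tolerance = 1e-6)
  expect_identical(equilibrium_pdf(m, 0, 95), 0)
})

test_that("higher precision concentrates the equilibrium (IQR decreases)", {
  iqrs <- vapply(c(0.5, 1, 1.5, 2), function(b)
    fluctlearn:::equilibrium_iqr(energy_model(beta = b)), numeric(1))
  expect_true(all(diff(iqrs) < 0))
})

test_that("equilibrium sampling is reproducible, bounded and distributed correctly", {
  m <- energy_model(beta = 1)
  s1 <- sample_equilibrium(m, 0, 1000, seed = 11)
  s2 <- sample_equilibrium(m, 0, 1000, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1 >= -90 & s1 <= 90))
  s <- sample_equilibrium(m, 0, 1e5, seed = 12)
  ks <- oracle_ks(s, oracle_cdf_fun(beta = 1))
  expect_lt(ks, 0.01)
})
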