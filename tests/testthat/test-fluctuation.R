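test_that("kernel density estimate matches its definition", {
  # single repeated value with fixed bandwidth: the kernel itself
  k <- fit_kde(rep(2, 5), bandwidth = "fixed", h = 0.7)
  at <- c(0, 1.5, 2, 3)
  expect_equal(predict(k, at), stats::dnorm(at, 2, 0.7), tolerance = 1e-12)
  # mirrored sample set gives a mirrored density
  set.seed(31)
  s <- stats::rnorm(200)
  ks <- fit_kde(s, bandwidth = "fixed", h = 0.4)
  km <- fit_kde(-s, bandwidth = "fixed", h = 0.4)
  w <- seq(-3, 3, by = 0.25)
  expect_lt(max(abs(predict(ks, w) - predict(km, -w))), 1e-10)
  # Monte-Carlo consistency against the closed-form normal density
  set.seed(32)
  big <- fit_kde(stats::rnorm(50000))
  grid <- seq(-3, 3, by = 0.1)
  expect_lt(max(abs(predict(big, grid) - stats::dnorm(grid))), 0.01)
  expect_error(fit_kde(rep(1, 10)), "degenerate")
  expect_error(fit_kde(1), ">= 2")
})

test_that("mirrored backward samples cancel the Crooks log-ratio", {
  set.seed(33)
  wf <- stats::rnorm(40, 1, 0.8)
  work <- list(forward = wf, backward = -wf)
  cc <- crooks_curve(work, n_boot = 10, seed = 1)
  expect_lt(max(abs(cc$plugin)), 1e-10)
  expect_equal(cc$theory, cc$grid)     # delta_F = 0
})

test_that("discrete-toy enumeration satisfies the fluctuation relation exactly", {
  dF <- toy_delta_F()
  expect_equal(dF, 0, tolerance = 1e-14)   # symmetric energies
  rf <- toy_work_distribution("F")
  rb <- toy_work_distribution("B")
  for (i in seq_along(rf$w)) {
    w <- rf$w[i]
    rho_b <- rb$rho[match(-w, rb$w)]
    expect_equal(log(rf$rho[i] / rho_b), w - dF, tolerance = 1e-12)
  }
  # KDE pipeline on sampled toy paths reproduces the relation approximately
  wf <- toy_sample_work(2e4, "F", seed = 34)
  wb <- toy_sample_work(2e4, "B", seed = 35)
  est <- log(predict(fit_kde(wf), rf$w)) - log(predict(fit_kde(wb), -rf$w))
  expect_lt(max(abs(est - rf$w)), 0.05)
})

test_that("Jarzynski estimator matches hand computations and flags consistency", {
  z <- list(forward = rep(0, 20), backward = rep(0, 20))
  jz <- jarzynski(z, n_boot = 50, seed = 2)
  expect_equal(jz$point_estimate, 1)
  expect_equal(c(jz$ci_low, jz$ci_high), c(1, 1))
  expect_true(jz$consistent)

  w2 <- list(forward = c(log(2), -log(2)))
  expect_equal(jarzynski(w2, n_boot = 10, seed = 3)$point_estimate, 1.25)

  expect_error(jarzynski(list(forward = numeric(0))), "degenerate")
})

test_that("bootstrap bands and intervals are seed-reproducible", {
  set.seed(36)
  work <- list(forward = stats::rnorm(20, 0.5), backward = stats::rnorm(20, 0.5))
  c1 <- crooks_curve(work, n_boot = 200, seed = 44)
  c2 <- crooks_curve(work, n_boot = 200, seed = 44)
  expect_identical(c1$estimate, c2$estimate)
  expect_identical(c1$band_low, c2$band_low)
  j1 <- jarzynski(work, n_boot = 500, seed = 45)
  j2 <- jarzynski(work, n_boot = 500, seed = 45)
  expect_identical(c(j1$ci_low, j1$ci_high), c(j2$ci_low, j2$ci_high))
  # percentile band brackets the bootstrap mean path
  expect_true(all(c1$band_low <= c1$estimate & c1$estimate <= c1$band_high))
})
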