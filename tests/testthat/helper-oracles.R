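# Independent numerical oracles: everything here evaluates the Boltzmann
# model directly from its defining formulas with stats::integrate, without
# going through the package's free_energy / equilibrium_* code paths.

oracle_energy <- function(x, theta, bias = 0) 1 - exp(-(x - (theta + bias))^2)

oracle_Z <- function(beta, theta, bias = 0, support = c(-90, 90)) {
  f <- function(x) exp(-beta * oracle_energy(x, theta, bias))
  # split at the well so adaptive quadrature cannot miss it
  c0 <- theta + bias
  cuts <- sort(unique(pmin(pmax(c(support[1], c0 - 10, c0 + 10, support[2]),
                                support[1]), support[2])))
  sum(vapply(seq_len(length(cuts) - 1), function(i)
    if (cuts[i + 1] > cuts[i])
      stats::integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-12)$value
    else 0, numeric(1)))
}

oracle_free_energy <- function(beta, theta, bias = 0, support = c(-90, 90)) {
  -log(oracle_Z(beta, theta, bias, support)) / beta
}

# Equilibrium CDF as an interpolating function, from dense trapezoid
# integration of exp(-beta E) (20001 points; error far below the KS
# tolerances it is used against).
oracle_cdf_fun <- function(beta, theta = 0, bias = 0, support = c(-90, 90)) {
  xs <- seq(support[1], support[2], length.out = 20001L)
  f <- exp(-beta * oracle_energy(xs, theta, bias))
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(xs)))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(xs, cdf, yleft = 0, yright = 1)
}

# One-sample KS distance of a sample against a vectorized CDF function.
oracle_ks <- function(sample, cdf_fun) {
  x <- sort(sample)
  Fi <- cdf_fun(x)
  n <- length(x)
  i <- seq_len(n)
  max(pmax(i / n - Fi, Fi - (i - 1) / n))
}
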