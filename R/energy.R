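#' Sensorimotor energy model
#'
#' Constructs the parametric sensorimotor loss ("energy") used throughout the
#' package. The default `exp_quad` kind is the exponential-quadratic error
#' \deqn{E(x; \theta) = 1 - e^{-(x - (\theta + b))^2},}
#' with the difference taken in raw degrees, which is zero at the (biased)
#' target \eqn{\theta + b} and saturates at 1 for large errors. The
#' `mexican_hat` kind is an inverted Ricker wavelet control loss,
#' \deqn{E(x; \theta) = (1 - u^2/\sigma^2)\, e^{-u^2/(2\sigma^2)}, \quad
#'   u = x - (\theta + b),}
#' which is *maximal* (worst) at the target — a deliberately mis-specified
#' loss used as a negative control.
#'
#' Steady-state behaviour under an energy model is the truncated Boltzmann
#' equilibrium \eqn{p^{eq}(x) \propto e^{-\beta E(x;\theta)}} on the support
#' interval, with `beta` (inverse temperature / precision) interpolating
#' between purely stochastic (\eqn{\beta \to 0}) and perfectly
#' error-minimizing (\eqn{\beta \to \infty}) responding.
#'
#' @param kind `"exp_quad"` or `"mexican_hat"`.
#' @param beta Inverse temperature, strictly positive. `beta = 0` is
#'   rejected: the purely stochastic limit is the truncated uniform
#'   distribution, which callers should model directly rather than as a
#'   degenerate Boltzmann equilibrium.
#' @param bias Participant-specific response bias \eqn{b} in degrees.
#' @param support Length-2 numeric, the closed support interval of the
#'   equilibrium distribution in degrees (finite, increasing).
#' @param sigma Width \eqn{\sigma} in degrees; required for
#'   `kind = "mexican_hat"`, ignored otherwise.
#' @return An object of class `energy_model`.
#' @examples
#' m <- energy_model(beta = 1)
#' evaluate_energy(m, x = 9, theta = 10)  # 1 - exp(-1)
#' @export
energy_model <- function(kind = c("exp_quad", "mexican_hat"), beta = 1,
                         bias = 0, support = c(-90, 90), sigma = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single finite value > 0 (the beta = 0 stochastic ",
         "limit is a truncated uniform, not a Boltzmann equilibrium)")
  if (!is.numeric(bias) || length(bias) != 1L || !is.finite(bias))
    stop("'bias' must be a single finite number (degrees)")
  if (!is.numeric(support) || length(support) != 2L || !all(is.finite(support)) ||
      support[1L] >= support[2L])
    stop("'support' must be a finite increasing interval c(lo, hi)")
  if (kind == "mexican_hat") {
    if (is.null(sigma) || !is.numeric(sigma) || length(sigma) != 1L ||
        !is.finite(sigma) || sigma <= 0)
      stop("'sigma' must be a single finite value > 0 for kind = 'mexican_hat'")
  } else {
    sigma <- NULL
  }
  structure(
    list(kind = kind, beta = beta, bias = bias,
         support = as.numeric(support), sigma = sigma),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Energy model: ", x$kind, "\n",
      "  beta (inverse temperature): ", format(x$beta), "\n",
      "  bias b: ", format(x$bias), " deg\n",
      "  support: [", x$support[1L], ", ", x$support[2L], "] deg\n", sep = "")
  if (!is.null(x$sigma)) cat("  sigma: ", format(x$sigma), " deg\n", sep = "")
  invisible(x)
}

is_energy_model <- function(x) inherits(x, "energy_model")

#' Evaluate the sensorimotor energy
#'
#' Evaluates \eqn{E(x;\theta)} for an [energy_model()]. Defined for all finite
#' `x`, inside or outside the support. Vectorized over `x` and `theta`
#' (recycled).
#'
#' @param model An [energy_model()].
#' @param x Response angle(s) in degrees.
#' @param theta Imposed rotation angle(s) in degrees.
#' @return Numeric vector of dimensionless energies; in `[0, 1)` for
#'   `exp_quad`.
#' @export
evaluate_energy <- function(model, x, theta) {
  stopifnot(is_energy_model(model))
  if (!is.numeric(x) || !is.numeric(theta) || !all(is.finite(x)) ||
      !all(is.finite(theta)))
    stop("'x' and 'theta' must be finite numeric (degrees)")
  u <- x - (theta + model$bias)
  switch(model$kind,
    exp_quad = 1 - exp(-u^2),
    mexican_hat = {
      s2 <- model$sigma^2
      (1 - u^2 / s2) * exp(-u^2 / (2 * s2))
    })
}

# Closure form of the energy, used in inner simulation loops.
energy_fun <- function(model) {
  b <- model$bias
  if (model$kind == "exp_quad") {
    function(x, theta) { u <- x - (theta + b); 1 - exp(-u^2) }
  } else {
    s2 <- model$sigma^2
    function(x, theta) { u <- x - (theta + b); (1 - u^2 / s2) * exp(-u^2 / (2 * s2)) }
  }
}

# Partition function Z = int_support exp(-beta E) dx by adaptive quadrature.
# The integrand can be a narrow spike around theta + bias at large beta, so the
# support is split at the spike before handing the pieces to stats::integrate.
partition_function <- function(model, theta) {
  efun <- energy_fun(model)
  f <- function(x) exp(-model$beta * efun(x, theta))
  lo <- model$support[1L]; hi <- model$support[2L]
  centre <- theta + model$bias
  half <- if (model$kind == "mexican_hat") 10 * model$sigma else 10
  cuts <- sort(unique(pmin(pmax(c(lo, centre - half, centre + half, hi), lo), hi)))
  z <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    if (cuts[i + 1L] <= cuts[i]) next
    piece <- tryCatch(
      stats::integrate(f, cuts[i], cuts[i + 1L], abs.tol = 1e-9,
                       rel.tol = 1e-10, subdivisions = 400L),
      error = function(e) stop("quadrature failed on [", cuts[i], ", ",
                               cuts[i + 1L], "]: ", conditionMessage(e)))
    z <- z + piece$value
  }
  if (!is.finite(z) || z <= 0)
    stop("quadrature returned a non-positive partition function (Z = ", z, ")")
  z
}

#' Free energy of the truncated Boltzmann equilibrium
#'
#' Computes \eqn{F(\theta) = -\frac{1}{\beta}\log \int_A e^{-\beta
#' E(x;\theta)}\,dx} by adaptive quadrature over the support \eqn{A}. The
#' sign is chosen so that the equilibrium density
#' \eqn{p^{eq}(x) = e^{-\beta(E(x;\theta) - F(\theta))}} normalizes to 1.
#'
#' @inheritParams evaluate_energy
#' @return Free energy (dimensionless), scalar per `theta` (vectorized).
#' @export
free_energy <- function(model, theta) {
  stopifnot(is_energy_model(model))
  if (!is.numeric(theta) || !all(is.finite(theta)))
    stop("'theta' must be finite numeric (degrees)")
  vapply(theta, function(th) -log(partition_function(model, th)) / model$beta,
         numeric(1L))
}

#' Equilibrium (Boltzmann) density
#'
#' Density \eqn{p^{eq}(x) = e^{-\beta(E(x;\theta) - F(\theta))}} of the
#' truncated Boltzmann equilibrium at rotation `theta`; zero outside the
#' support. Integrates to 1 over the support.
#'
#' @inheritParams evaluate_energy
#' @return Density values (per degree), vectorized over `x`.
#' @export
equilibrium_pdf <- function(model, theta, x) {
  stopifnot(is_energy_model(model), length(theta) == 1L)
  F <- free_energy(model, theta)
  d <- exp(-model$beta * (evaluate_energy(model, x, theta) - F))
  d[x < model$support[1L] | x > model$support[2L]] <- 0
  d
}

# Dense grid representation of the equilibrium: uniform grid over the support
# refined around the energy extremum, with trapezoid CDF. Backbone of the
# inverse-CDF sampler, the CDF evaluator and the IQR helper.
equilibrium_grid <- function(model, theta, n = 4096L) {
  lo <- model$support[1L]; hi <- model$support[2L]
  centre <- theta + model$bias
  xs <- seq(lo, hi, length.out = n)
  if (centre > lo && centre < hi) {
    fine <- seq(max(lo, centre - 10), min(hi, centre + 10), length.out = 1024L)
    xs <- sort(unique(c(xs, fine)))
  }
  pdf <- equilibrium_pdf(model, theta, xs)
  dx <- diff(xs)
  cdf <- c(0, cumsum((pdf[-1L] + pdf[-length(pdf)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  list(x = xs, pdf = pdf, cdf = cdf)
}

#' Equilibrium cumulative distribution function
#'
#' CDF of the truncated Boltzmann equilibrium, computed by trapezoid
#' integration of [equilibrium_pdf()] on a dense grid.
#'
#' @inheritParams evaluate_energy
#' @return CDF values in `[0, 1]`, vectorized over `x`.
#' @export
equilibrium_cdf <- function(model, theta, x) {
  g <- equilibrium_grid(model, theta)
  stats::approx(g$x, g$cdf, xout = x, yleft = 0, yright = 1, rule = 2)$y
}

#' Sample from the equilibrium distribution
#'
#' Draws i.i.d. responses from the truncated Boltzmann equilibrium by
#' inverse-CDF sampling on a dense grid (4096 uniform points plus a
#' refinement around the energy extremum).
#'
#' @inheritParams evaluate_energy
#' @param n Number of draws.
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   draw is reproducible.
#' @return Numeric vector of `n` angles in degrees, all within the support.
#' @export
sample_equilibrium <- function(model, theta, n, seed = NULL) {
  stopifnot(is_energy_model(model), length(theta) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  g <- equilibrium_grid(model, theta)
  u <- stats::runif(n)
  # strictly increasing CDF knots only, for a well-defined inverse
  keep <- c(TRUE, diff(g$cdf) > 0)
  stats::approx(g$cdf[keep], g$x[keep], xout = u, rule = 2)$y
}

# Interquartile range of the equilibrium, from the grid CDF.
equilibrium_iqr <- function(model, theta = 0) {
  g <- equilibrium_grid(model, theta)
  keep <- c(TRUE, diff(g$cdf) > 0)
  q <- stats::approx(g$cdf[keep], g$x[keep], xout = c(0.25, 0.75), rule = 2)$y
  diff(q)
}
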