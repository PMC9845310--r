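#' Fit the equilibrium model to a participant's baseline block
#'
#' Maximum-likelihood reconstruction of the per-participant Boltzmann
#' equilibrium from the unperturbed baseline trials (recorded at
#' \eqn{\theta = 0}): the bias is estimated by the sample mean,
#' \eqn{\hat b = \bar x}; the support defaults to \eqn{[\hat b - 90,
#' \hat b + 90]} (the standard simulation support, recentred on the bias) or
#' can be taken from the data (min/max padded by 5 degrees); the inverse
#' temperature \eqn{\hat\beta} maximizes the equilibrium log-likelihood
#' \eqn{\sum_i \log p^{eq}(x_i; \theta = 0)} by bounded one-dimensional
#' search on \eqn{\log \beta}.
#'
#' The fit is deliberately isolated behind this one function so an
#' alternative fitting procedure can be substituted without touching the
#' rest of the pipeline.
#'
#' @param baseline_responses Response angles (degrees) of the baseline
#'   block; at least 10.
#' @param support Optional explicit support interval (degrees); overrides
#'   `support_rule`.
#' @param support_rule `"recentred"` (default, \eqn{\hat b \pm 90}) or
#'   `"data"` (observed range padded by 5 degrees).
#' @param beta_range Search interval for \eqn{\beta}.
#' @return An object of class `participant_fit`: `beta_hat`, `bias_hat`,
#'   `support_hat`, `n_baseline`, `loglik`, `at_bound` (`"none"`,
#'   `"lower"`, or `"upper"`; a warning is also raised when the optimizer
#'   pins \eqn{\hat\beta} at a bound), and the implied [energy_model()] as
#'   `model`.
#' @export
fit_participant <- function(baseline_responses, support = NULL,
                            support_rule = c("recentred", "data"),
                            beta_range = c(0.01, 100)) {
  support_rule <- match.arg(support_rule)
  x <- baseline_responses
  if (!is.numeric(x) || length(x) < 10L || !all(is.finite(x)))
    stop("degenerate data: need >= 10 finite baseline responses")
  bias_hat <- mean(x)
  if (is.null(support)) {
    support <- if (support_rule == "recentred")
      range(c(bias_hat - 90, bias_hat + 90, x))   # widened if data spill over
    else range(x) + c(-5, 5)
  }
  if (any(x < support[1L]) || any(x > support[2L]))
    stop("support [", support[1L], ", ", support[2L],
         "] does not contain all baseline responses")

  # log-lik(beta) = -beta * sum(E_i) + n * beta * F(beta); E_i fixed in beta
  Ei <- 1 - exp(-(x - bias_hat)^2)
  sumE <- sum(Ei); n <- length(x)
  nll <- function(logbeta) {
    beta <- exp(logbeta)
    m <- energy_model("exp_quad", beta = beta, bias = bias_hat,
                      support = support)
    F <- free_energy(m, theta = 0)
    -(-beta * sumE + n * beta * F)
  }
  opt <- stats::optimize(nll, interval = log(beta_range), tol = 1e-6)
  beta_hat <- exp(opt$minimum)

  # optimize() cannot land exactly on an endpoint; treat a relative
  # neighbourhood of the bounds as "pinned"
  at_bound <- if (beta_hat <= beta_range[1L] * 1.01) "lower"
              else if (beta_hat >= beta_range[2L] * 0.99) "upper"
              else "none"
  if (at_bound != "none")
    warning("beta_hat pinned at the ", at_bound, " bound of the search ",
            "interval [", beta_range[1L], ", ", beta_range[2L], "]; the ",
            "baseline data are ",
            if (at_bound == "lower") "near-uniform" else "near-degenerate")

  structure(
    list(beta_hat = beta_hat, bias_hat = bias_hat,
         support_hat = as.numeric(support), n_baseline = n,
         loglik = -opt$objective, at_bound = at_bound,
         model = energy_model("exp_quad", beta = beta_hat, bias = bias_hat,
                              support = support)),
    class = "participant_fit"
  )
}

#' @export
print.participant_fit <- function(x, ...) {
  cat("Participant equilibrium fit (", x$n_baseline, " baseline trials)\n",
      "  beta_hat = ", sprintf("%.4f", x$beta_hat),
      if (x$at_bound != "none") paste0("  [pinned at ", x$at_bound, " bound]"),
      "\n  bias_hat = ", sprintf("%.3f", x$bias_hat), " deg\n",
      "  support  = [", sprintf("%.1f", x$support_hat[1L]), ", ",
      sprintf("%.1f", x$support_hat[2L]), "] deg\n", sep = "")
  invisible(x)
}

# One-sample Kolmogorov-Smirnov distance between a sample and a CDF given as
# values at the sorted sample points.
ks_statistic <- function(sample, cdf_values) {
  ord <- order(sample)
  Fi <- cdf_values[ord]
  n <- length(sample)
  i <- seq_len(n)
  max(pmax(i / n - Fi, Fi - (i - 1) / n))
}

#' Check equilibration on washout plateaus
#'
#' Compares the distribution of responses during washout plateaus
#' (\eqn{\theta = 0} trials between the forward and backward segments)
#' against the participant's fitted equilibrium, via the Kolmogorov-Smirnov
#' distance to the fitted equilibrium CDF. Re-equilibration between
#' segments is a premise of the fluctuation-theorem analysis; this is a
#' diagnostic (no p-value is claimed — plateau trials are serially
#' dependent).
#'
#' @param plateau_responses Response angles (degrees) on plateau trials; at
#'   least 10.
#' @param fit A [fit_participant()] result (or any list with a `model`
#'   element that is an [energy_model()]).
#' @param threshold KS-distance below which the check passes.
#' @return An object of class `equilibration_report`: `ks_distance`,
#'   `n_plateau`, `threshold`, `pass`.
#' @export
equilibration_check <- function(plateau_responses, fit, threshold = 0.1) {
  x <- plateau_responses
  if (!is.numeric(x) || length(x) < 10L || !all(is.finite(x)))
    stop("degenerate data: need >= 10 finite plateau responses")
  model <- if (is_energy_model(fit)) fit else fit$model
  stopifnot(is_energy_model(model))
  d <- ks_statistic(x, equilibrium_cdf(model, theta = 0, x = x))
  structure(
    list(ks_distance = d, n_plateau = length(x), threshold = threshold,
         pass = d < threshold),
    class = "equilibration_report"
  )
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat("Washout equilibration check: KS distance ",
      sprintf("%.4f", x$ks_distance), " over ", x$n_plateau,
      " plateau trials (threshold ", x$threshold, "): ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}
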