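#' Metropolis-Hastings learner configuration
#'
#' Settings for the synthetic bounded-rational learner: a Markov chain whose
#' per-trial transition kernel is one or more Metropolis-Hastings steps
#' targeting the current trial's Boltzmann equilibrium
#' \eqn{p^{eq}_n \propto e^{-\beta E_n}}. The kernel satisfies detailed
#' balance with respect to \eqn{p^{eq}_n}, which is the structural premise
#' of the fluctuation-theorem analysis.
#'
#' @param proposal_scale Standard deviation (degrees) of the symmetric
#'   Gaussian random-walk proposal.
#' @param steps_per_trial Number of MH transitions applied per trial; the
#'   state after the last one is the recorded response.
#' @param init `"equilibrium"` (draw the initial response from the first
#'   trial's equilibrium) or `"fixed"` (start at `init_value`).
#' @param init_value Initial response in degrees when `init = "fixed"`.
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(proposal_scale = 10, steps_per_trial = 3,
                           init = c("equilibrium", "fixed"), init_value = 0) {
  init <- match.arg(init)
  if (!is.numeric(proposal_scale) || length(proposal_scale) != 1L ||
      !is.finite(proposal_scale) || proposal_scale <= 0)
    stop("'proposal_scale' must be a single finite value > 0 (degrees)")
  if (!is.numeric(steps_per_trial) || length(steps_per_trial) != 1L ||
      steps_per_trial < 1)
    stop("'steps_per_trial' must be a count >= 1")
  structure(
    list(proposal_scale = proposal_scale,
         steps_per_trial = as.integer(steps_per_trial),
         init = init, init_value = init_value),
    class = "learner_config"
  )
}

#' One Metropolis-Hastings transition of the learner
#'
#' Applies a single MH step at rotation `theta`: propose
#' \eqn{x' = x + \epsilon}, \eqn{\epsilon \sim N(0,
#' \mathrm{proposal\_scale}^2)}; reject (stay at `x`) if \eqn{x'} falls
#' outside the support; otherwise accept with probability
#' \eqn{\min(1, e^{-\beta (E(x';\theta) - E(x;\theta))})}. Because the
#' proposal is symmetric and out-of-support proposals are rejected
#' symmetrically, the kernel satisfies detailed balance with respect to
#' [equilibrium_pdf()].
#'
#' Uses the current R random-number stream; seed it with `set.seed()` for
#' reproducibility.
#'
#' @inheritParams evaluate_energy
#' @param x Current response (degrees); must lie within the support.
#' @param config A [learner_config()].
#' @param proposal Optional forced proposal value (degrees), bypassing the
#'   random draw; intended for deterministic testing of the acceptance rule.
#' @return The next response angle (degrees).
#' @export
mh_step <- function(model, theta, x, config = learner_config(),
                    proposal = NULL) {
  stopifnot(is_energy_model(model), inherits(config, "learner_config"))
  if (x < model$support[1L] || x > model$support[2L])
    stop("current state x = ", x, " lies outside the support [",
         model$support[1L], ", ", model$support[2L], "]")
  xp <- if (is.null(proposal)) x + stats::rnorm(1L, 0, config$proposal_scale)
        else proposal
  if (xp < model$support[1L] || xp > model$support[2L]) return(x)
  dE <- evaluate_energy(model, xp, theta) - evaluate_energy(model, x, theta)
  if (dE <= 0 || stats::runif(1L) < exp(-model$beta * dE)) xp else x
}

#' Simulate a learner through a rotation protocol
#'
#' Runs the Metropolis-Hastings learner through every trial of a protocol
#' (baseline block plus all cycles). The chain starts in equilibrium for the
#' first trial's rotation (or at a fixed value, per the config); on each
#' trial it takes `steps_per_trial` MH transitions under that trial's
#' \eqn{\theta} and the final state is recorded as the response \eqn{x_n}.
#'
#' @inheritParams mh_step
#' @param protocol An [build_protocol()] object.
#' @param seed Integer seed; the run is fully reproducible given
#'   (`model`, `protocol`, `config`, `seed`).
#' @param participant_id Label stored in the returned trial table.
#' @return A `trial_data` data frame (see [read_trials()] for the column
#'   contract) with one row per trial, with attributes `seed` and `source =
#'   "simulated"`.
#' @examples
#' m <- energy_model(beta = 1)
#' p <- build_protocol(n_cycles = 2, baseline_length = 10)
#' td <- simulate_run(m, p, learner_config(), seed = 1)
#' head(td)
#' @export
simulate_run <- function(model, protocol, config = learner_config(), seed,
                         participant_id = "sim") {
  stopifnot(is_energy_model(model), is_protocol(protocol),
            inherits(config, "learner_config"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' (single integer) is required for a reproducible run")
  set.seed(seed)

  thetas <- protocol$angles
  n <- length(thetas)
  k <- config$steps_per_trial
  efun <- energy_fun(model)
  lo <- model$support[1L]; hi <- model$support[2L]
  beta <- model$beta

  x <- if (config$init == "equilibrium")
    sample_equilibrium(model, thetas[1L], 1L) else config$init_value
  if (x < lo || x > hi)
    stop("initial response ", x, " lies outside the support")

  # all proposal increments / acceptance uniforms drawn up-front, one column
  # per trial, so the inner loop is pure arithmetic
  eps <- matrix(stats::rnorm(n * k, 0, config$proposal_scale), nrow = k)
  us <- matrix(stats::runif(n * k), nrow = k)

  responses <- numeric(n)
  Ex <- efun(x, thetas[1L])
  for (i in seq_len(n)) {
    th <- thetas[i]
    Ex <- efun(x, th)
    for (s in seq_len(k)) {
      xp <- x + eps[s, i]
      if (xp < lo || xp > hi) next
      Exp <- efun(xp, th)
      if (Exp <= Ex || us[s, i] < exp(-beta * (Exp - Ex))) {
        x <- xp
        Ex <- Exp
      }
    }
    responses[i] <- x
  }

  trials <- trial_table(protocol, responses, participant_id)
  attr(trials, "seed") <- seed
  attr(trials, "source") <- "simulated"
  trials
}

# Assemble the canonical trial table for a protocol-aligned response vector.
trial_table <- function(protocol, responses, participant_id) {
  if (length(responses) != length(protocol$angles))
    stop("responses (", length(responses), ") do not match protocol length (",
         length(protocol$angles), ")")
  nb <- protocol$baseline_length
  nc <- protocol$n_cycles
  cl <- protocol$cycle_length
  out <- data.frame(
    participant_id = participant_id,
    block = c(rep("baseline", nb), rep("main", nc * cl)),
    cycle = c(rep(0L, nb), rep(seq_len(nc), each = cl)),
    trial_index = c(seq_len(nb), rep(seq_len(cl), nc)),
    theta_deg = protocol$angles,
    response_deg = responses,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_data", "data.frame")
  out
}
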