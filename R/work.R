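#' Externally driven energy change (driving error)
#'
#' Cumulative energy change caused by the environment changing the rotation
#' while the response is held fixed — the work analogue that drives
#' adaptation:
#' \deqn{\Delta E_{ext}(\mathbf{x}) = \sum_{n=0}^{N-1}
#'   \big(E_{n+1}(x_n) - E_n(x_n)\big).}
#'
#' @param model An [energy_model()].
#' @param thetas Rotation angles \eqn{\theta_0, \ldots, \theta_N} (degrees).
#' @param xs Responses \eqn{x_0, \ldots, x_N} (degrees), same length.
#' @return Dimensionless driving-error value.
#' @export
external_work <- function(model, thetas, xs) {
  check_segment(thetas, xs)
  n <- length(xs)
  sum(evaluate_energy(model, xs[-n], thetas[-1L]) -
      evaluate_energy(model, xs[-n], thetas[-n]))
}

#' Internally generated energy change (adaptation heat)
#'
#' Cumulative energy change caused by the learner updating its response
#' under a fixed environment — the heat analogue:
#' \deqn{\Delta E_{int}(\mathbf{x}) = \sum_{n=1}^{N}
#'   \big(E_n(x_n) - E_n(x_{n-1})\big).}
#' Together with [external_work()] it satisfies the first-law identity
#' \eqn{\Delta E_{ext} + \Delta E_{int} = E_N(x_N) - E_0(x_0)}.
#'
#' @inheritParams external_work
#' @return Dimensionless heat value.
#' @export
internal_heat <- function(model, thetas, xs) {
  check_segment(thetas, xs)
  n <- length(xs)
  sum(evaluate_energy(model, xs[-1L], thetas[-1L]) -
      evaluate_energy(model, xs[-n], thetas[-1L]))
}

check_segment <- function(thetas, xs) {
  if (!is.numeric(thetas) || !is.numeric(xs) ||
      !all(is.finite(thetas)) || !all(is.finite(xs)))
    stop("'thetas' and 'xs' must be finite numeric (degrees)")
  if (length(thetas) != length(xs))
    stop("'thetas' (", length(thetas), ") and 'xs' (", length(xs),
         ") must have equal length")
  if (length(xs) < 2L)
    stop("a segment needs at least 2 trials")
  invisible(TRUE)
}

#' Per-cycle driving-error samples for the forward and backward processes
#'
#' For each cycle of the protocol, computes [external_work()] over the
#' forward segment and over the backward segment of a protocol-aligned
#' trajectory, yielding one forward and one backward \eqn{\Delta E_{ext}}
#' realization per cycle. Transitions are taken strictly inside each
#' segment (the \eqn{\theta}-step from the preceding plateau into the
#' segment is not charged; both segments start and end at \eqn{\theta = 0},
#' so \eqn{\Delta F = 0} either way).
#'
#' @param model An [energy_model()].
#' @param protocol An [build_protocol()] object.
#' @param trials A `trial_data` table (from [simulate_run()] or
#'   [read_trials()]) for a single participant, aligned to `protocol`.
#' @return An object of class `work_samples`: list with numeric vectors
#'   `forward` and `backward` (one value per cycle), `participant_id`, and
#'   the `model` used.
#' @export
extract_work_samples <- function(model, protocol, trials) {
  stopifnot(is_energy_model(model), is_protocol(protocol))
  trials <- check_trials(trials)
  ids <- unique(trials$participant_id)
  if (length(ids) != 1L)
    stop("'trials' must contain a single participant; got ",
         length(ids), " (split first)")
  n_expected <- protocol$baseline_length +
    protocol$n_cycles * protocol$cycle_length
  if (nrow(trials) != n_expected)
    stop("trajectory (", nrow(trials), " trials) is not aligned to the ",
         "protocol (", n_expected, " trials expected)")

  per_cycle <- function(range) {
    vapply(seq_len(protocol$n_cycles), function(cy) {
      idx <- cycle_trial_index(protocol, cy, range)
      external_work(model, trials$theta_deg[idx], trials$response_deg[idx])
    }, numeric(1L))
  }
  structure(
    list(forward = per_cycle(protocol$forward_range),
         backward = per_cycle(protocol$backward_range),
         participant_id = ids, model = model),
    class = "work_samples"
  )
}

#' @export
print.work_samples <- function(x, ...) {
  cat("Driving-error samples for participant '", x$participant_id, "': ",
      length(x$forward), " cycles\n", sep = "")
  cat("  forward : ", paste(sprintf("%.3f", utils::head(x$forward, 6L)),
                            collapse = " "),
      if (length(x$forward) > 6L) " ..." else "", "\n", sep = "")
  cat("  backward: ", paste(sprintf("%.3f", utils::head(x$backward, 6L)),
                            collapse = " "),
      if (length(x$backward) > 6L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Export driving-error samples as a tidy table
#'
#' @param work A `work_samples` object.
#' @return Data frame with columns `participant_id`, `cycle`, `direction`
#'   (`"F"`/`"B"`), `delta_E_ext`.
#' @export
work_samples_table <- function(work) {
  stopifnot(inherits(work, "work_samples"))
  n <- length(work$forward)
  data.frame(
    participant_id = work$participant_id,
    cycle = rep(seq_len(n), 2L),
    direction = rep(c("F", "B"), each = n),
    delta_E_ext = c(work$forward, work$backward),
    stringsAsFactors = FALSE
  )
}
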