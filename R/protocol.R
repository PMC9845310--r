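#' Build a cyclic forward/backward rotation protocol
#'
#' Constructs the deterministic sequence of imposed rotation angles
#' \eqn{\theta_n} for a visuomotor rotation experiment: an unperturbed
#' baseline block (\eqn{\theta = 0}), then `n_cycles` identical cycles, each
#' consisting of a forward segment, a washout plateau at \eqn{\theta = 0},
#' the backward segment (the forward angles in reversed order), and a second
#' washout plateau.
#'
#' The default forward segment is a 25-trial triangular excursion
#' \eqn{0 \to +\theta_{peak} \to -\theta_{peak} \to 0} in equal angular
#' steps, giving the standard cycle layout: forward trials 1–25, plateau
#' 26–33, backward trials 34–58, plateau 59–66 (66 trials per cycle). An
#' arbitrary forward segment can be supplied via `forward_angles`; it must
#' start and end at 0 so that the free-energy difference over each segment
#' is zero.
#'
#' @param theta_peak Peak rotation in degrees (> 0 unless a degenerate
#'   all-zero protocol is intended). Ignored when `forward_angles` is given.
#' @param forward_length Number of trials in the forward segment (odd
#'   lengths ≥ 5 recommended so the triangle is symmetric). Ignored when
#'   `forward_angles` is given.
#' @param plateau_length Number of washout trials (\eqn{\theta = 0}) after
#'   each of the forward and backward segments.
#' @param n_cycles Number of cycles.
#' @param baseline_length Number of unperturbed trials before the first
#'   cycle.
#' @param forward_angles Optional explicit forward-segment angles (degrees).
#' @return An object of class `adaptation_protocol` with elements
#'   `cycle_angles`, `angles` (full \eqn{\theta} sequence including the
#'   baseline), `forward_range` and `backward_range` (1-based trial indices
#'   within a cycle), `cycle_length`, `n_cycles`, `baseline_length`,
#'   `theta_peak`.
#' @examples
#' p <- build_protocol()
#' p$cycle_length          # 66
#' p$forward_range         # 1 25
#' p$backward_range        # 34 58
#' @export
build_protocol <- function(theta_peak = 30, forward_length = 25,
                           plateau_length = 8, n_cycles = 20,
                           baseline_length = 100, forward_angles = NULL) {
  if (is.null(forward_angles)) {
    if (!is.numeric(theta_peak) || length(theta_peak) != 1L ||
        !is.finite(theta_peak) || theta_peak < 0)
      stop("'theta_peak' must be a single finite value >= 0")
    if (forward_length < 5L)
      stop("'forward_length' must be >= 5 for the default triangular excursion")
    forward_angles <- triangular_excursion(theta_peak, forward_length)
  } else {
    if (!is.numeric(forward_angles) || !all(is.finite(forward_angles)))
      stop("'forward_angles' must be finite numeric (degrees)")
    if (forward_angles[1L] != 0 ||
        forward_angles[length(forward_angles)] != 0)
      stop("'forward_angles' must start and end at 0 so that the ",
           "free-energy difference over each segment is zero")
    forward_length <- length(forward_angles)
    theta_peak <- max(abs(forward_angles))
  }
  if (plateau_length < 1L) stop("'plateau_length' must be >= 1")
  if (n_cycles < 1L) stop("'n_cycles' must be >= 1")
  if (baseline_length < 0L) stop("'baseline_length' must be >= 0")

  backward_angles <- rev(forward_angles)
  cycle_angles <- c(forward_angles, rep(0, plateau_length),
                    backward_angles, rep(0, plateau_length))
  L <- forward_length
  structure(
    list(cycle_angles = cycle_angles,
         angles = c(rep(0, baseline_length), rep(cycle_angles, n_cycles)),
         forward_range = c(1L, L),
         backward_range = c(L + plateau_length + 1L, 2L * L + plateau_length),
         cycle_length = length(cycle_angles),
         n_cycles = as.integer(n_cycles),
         baseline_length = as.integer(baseline_length),
         plateau_length = as.integer(plateau_length),
         theta_peak = theta_peak),
    class = "adaptation_protocol"
  )
}

# Symmetric triangular excursion 0 -> +peak -> -peak -> 0 over `length` trials
# in equal angular steps (piecewise-linear triangle wave sampled at the trial
# positions; the peak is attained exactly when (length - 1) is divisible by 4,
# as in the default 25-trial segment).
triangular_excursion <- function(peak, length) {
  if (peak == 0) return(rep(0, length))
  f <- (seq_len(length) - 1) / (length - 1)
  tri <- ifelse(f <= 0.25, 4 * f, ifelse(f <= 0.75, 2 - 4 * f, 4 * f - 4))
  peak * tri
}

#' @export
print.adaptation_protocol <- function(x, ...) {
  cat("Rotation protocol: ", x$n_cycles, " cycles x ", x$cycle_length,
      " trials (+", x$baseline_length, " baseline trials)\n",
      "  forward trials ", x$forward_range[1L], "-", x$forward_range[2L],
      ", backward trials ", x$backward_range[1L], "-", x$backward_range[2L],
      ", theta_peak ", x$theta_peak, " deg\n", sep = "")
  invisible(x)
}

is_protocol <- function(x) inherits(x, "adaptation_protocol")

# Global (1-based) trial indices of cycle `cycle` restricted to a within-cycle
# range, accounting for the baseline block.
cycle_trial_index <- function(protocol, cycle, range) {
  offset <- protocol$baseline_length + (cycle - 1L) * protocol$cycle_length
  offset + seq.int(range[1L], range[2L])
}

# Within-cycle indices of washout-plateau trials.
plateau_index <- function(protocol) {
  setdiff(seq_len(protocol$cycle_length),
          c(seq.int(protocol$forward_range[1L], protocol$forward_range[2L]),
            seq.int(protocol$backward_range[1L], protocol$backward_range[2L])))
}
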