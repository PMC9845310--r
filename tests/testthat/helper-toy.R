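# Three-state discrete-chain toy with a single environment switch, small
# enough for exact path enumeration. Used as the independent oracle for the
# log-density-ratio fluctuation relation: the chain starts in the equilibrium
# of environment 0, the environment switches (charging the driving error
# w(x0) = E1[x0] - E0[x0]), then one detailed-balance Metropolis transition
# under environment 1 completes the path (x0, x1). The reverse protocol
# starts in equilibrium of environment 1 and switches back.

toy_energies <- function() list(E0 = c(0, 0.5, 1), E1 = c(1, 0.5, 0))

toy_equilibrium <- function(E, beta = 1) {
  p <- exp(-beta * E)
  p / sum(p)
}

# Metropolis transition matrix on 3 states: propose one of the other two
# states uniformly, accept with min(1, exp(-beta dE)).
toy_transition <- function(E, beta = 1) {
  n <- length(E)
  T <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    T[i, j] <- 0.5 * min(1, exp(-beta * (E[j] - E[i])))
  }
  diag(T) <- 1 - rowSums(T)
  T
}

# Exact distribution of the driving error under forward (env 0 -> 1) or
# backward (env 1 -> 0) protocol, by enumeration of all (x0, x1) paths.
toy_work_distribution <- function(direction = c("F", "B"), beta = 1) {
  direction <- match.arg(direction)
  en <- toy_energies()
  if (direction == "F") {
    p0 <- toy_equilibrium(en$E0, beta); T <- toy_transition(en$E1, beta)
    w_of_state <- en$E1 - en$E0
  } else {
    p0 <- toy_equilibrium(en$E1, beta); T <- toy_transition(en$E0, beta)
    w_of_state <- en$E0 - en$E1
  }
  probs <- numeric(0)
  works <- numeric(0)
  for (x0 in 1:3) for (x1 in 1:3) {
    probs <- c(probs, p0[x0] * T[x0, x1])
    works <- c(works, w_of_state[x0])
  }
  w <- sort(unique(works))
  rho <- vapply(w, function(wi) sum(probs[works == wi]), numeric(1))
  list(w = w, rho = rho)
}

toy_delta_F <- function(beta = 1) {
  en <- toy_energies()
  (-log(sum(exp(-beta * en$E1))) + log(sum(exp(-beta * en$E0)))) / beta
}

# Sample n paths and return their driving-error values.
toy_sample_work <- function(n, direction = c("F", "B"), beta = 1,
                            seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  en <- toy_energies()
  if (direction == "F") {
    p0 <- toy_equilibrium(en$E0, beta); w_of_state <- en$E1 - en$E0
  } else {
    p0 <- toy_equilibrium(en$E1, beta); w_of_state <- en$E0 - en$E1
  }
  x0 <- sample.int(3, n, replace = TRUE, prob = p0)
  w_of_state[x0]   # the transition does not change the work; x1 marginalizes out
}
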