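---
title: "Fluctuation theorems for sensorimotor adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation theorems for sensorimotor adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctlearn)
```

## The model

In a visuomotor rotation task a participant reaches toward a target while
the cursor is rotated by an angle $\theta_n$ on trial $n$; the movement
direction $x_n$ (in degrees) is the behavioural response. The deviation
from the rotated target incurs a sensorimotor loss, treated as an energy:

$$E_n(x) = 1 - e^{-(x - (\theta_n + b))^2},$$

with the difference taken in raw degrees and $b$ a participant-specific
bias. The loss is quadratic near the target and saturates at 1 a few
degrees away, consistent with loss functions inferred for human pointing.
A bounded-rational learner that soft-minimizes this loss under an entropy
constraint settles, after sufficient exposure to one environment, into the
truncated Boltzmann equilibrium

$$p^{eq}_n(x) = e^{-\beta\,(E_n(x) - F_n)}, \qquad
  F_n = -\tfrac{1}{\beta}\log \int_{A} e^{-\beta E_n(x)}\,dx,$$

on a bounded support $A$. The inverse temperature $\beta$ interpolates
between purely stochastic responding ($\beta \to 0$, a truncated uniform —
rejected by `energy_model()` as a degenerate special case) and perfect
error minimization ($\beta \to \infty$). Note the sign of $F_n$: it is
chosen so that $p^{eq}_n$ integrates to one. An inverted-Ricker
("Mexican hat") loss with width $\sigma$, maximal at the target, is
provided as a deliberately mis-specified control; its exact closed form is
a package choice (the control only requires a loss that penalizes the
target region), selected by `energy_model(kind = "mexican_hat")` so an
alternative can be swapped in.

## Driving error and adaptation heat

Over a trajectory $\mathbf{x} = (x_0, \ldots, x_N)$ the total energy
change splits exactly into an externally driven part (the environment
moved under a fixed response) and an internal part (the learner moved
under a fixed environment):

$$\Delta E_{ext}(\mathbf{x}) = \sum_{n=0}^{N-1} \big(E_{n+1}(x_n) - E_n(x_n)\big),
\qquad
\Delta E_{int}(\mathbf{x}) = \sum_{n=1}^{N} \big(E_n(x_n) - E_n(x_{n-1})\big),$$

the analogues of work and heat. Their sum telescopes to
$E_N(x_N) - E_0(x_0)$ (tested to $10^{-12}$). For a Markov learner whose
transitions satisfy detailed balance with respect to the per-trial
equilibria and whose initial state is equilibrated, the driving error
obeys the work-value form of Crooks' fluctuation theorem

$$\Delta E_{ext} - \Delta F =
  \tfrac{1}{\beta}\log\frac{\rho^F(\Delta E_{ext})}{\rho^B(-\Delta E_{ext})}$$

and, as a corollary, Jarzynski's equality
$\langle e^{-\beta \Delta E_{ext}} \rangle = e^{-\beta \Delta F}$. Here
$\rho^F$ and $\rho^B$ are the distributions of the driving error under the
forward and the reversed (backward) presentation of the same environments.
In the protocols below every segment starts and ends at $\theta = 0$, so
$\Delta F = 0$ and the predicted exponentiated-work average is exactly 1.

## Protocol and segment conventions

`build_protocol()` constructs a 100-trial unperturbed baseline followed by
cycles of 66 trials: a 25-trial forward segment, an 8-trial washout
plateau at $\theta = 0$, the backward segment (the forward angles
reversed), and a second plateau. The default forward segment is a
triangular excursion $0 \to +30^\circ \to -30^\circ \to 0$ in $5^\circ$
steps. The exact excursion shape is configurable; the non-monotonic
triangle is the default because the characteristic hysteresis pattern —
forward means below backward means on rising limbs and above on the
falling limb — requires the protocol to revisit angles from both
directions. Driving errors are accumulated strictly inside each segment
(the $\theta$-step from a plateau into a segment is not charged); since
segments begin and end at $\theta = 0$, this convention does not affect
$\Delta F = 0$.

## The synthetic learner

`simulate_run()` drives a Metropolis–Hastings chain through the protocol:
on each trial it takes `steps_per_trial` transitions targeting that
trial's equilibrium, with a symmetric Gaussian proposal
(`proposal_scale`, degrees) and rejection of proposals outside the
support. Detailed balance holds by construction, and the run starts from
an equilibrium draw, so the simulated learner satisfies the premises of
the theorems exactly at the transition level. Defaults are
`proposal_scale = 10`, `steps_per_trial = 3`, chosen so that 20-cycle runs
at $\beta = 1$ produce driving errors essentially confined to
$|\Delta E_{ext}| \le 4$, the region where empirical adaptation data live,
while washout plateaus re-equilibrate the chain (pooled plateau responses
match the $\theta = 0$ equilibrium to a Kolmogorov–Smirnov distance well
under 0.05).

What the generator emulates: Markovian trial-to-trial dynamics, per-trial
Boltzmann equilibria, re-equilibration during washouts, and
between-participant variability ($\beta$, $b$ drawn per participant). What
it does not emulate: human coarse tracking. A person who compensates half
of a $30^\circ$ rotation with several degrees of motor noise produces a
response distribution that is broad on the scale of the 1°-wide energy
well, yet centred far from zero. The Metropolis learner's marginal is
always a mixture of a sharp well-locked component and a near-uniform
exploratory component — it can be *locked* (high $\beta$, many fine
steps) or *diffuse* (low $\beta$), but never "broadly tracking". This
difference matters for what passing tests show about real data; see
*Limitations*.

The simulated cohort used for the negative controls draws
$\beta \sim U[6, 12]$ and $b \sim U[-3, 3]$ per participant and uses a
finer learner (`proposal_scale = 5`, `steps_per_trial = 300`). The
$\beta$ range follows from the equilibrium geometry: the well must carry
most of the equilibrium mass before the mean response tracks the rotation
at all, which on a $[-90, 90]$ support requires $\beta \gtrsim 6$. The
fine stepping is required for the chain to stay captured by a well that
moves $5^\circ$ per trial; with the coarse default learner a
high-$\beta$ chain detaches immediately and adapts at chance level. With
these settings the cohort's median adaptation fraction is about 0.7 and
nearly all participants exceed the 50% criterion.

## Estimation

**Kernel density estimation.** `fit_kde()` uses Gaussian kernels with
Silverman's rule-of-thumb bandwidth (`stats::bw.nrd0`); a fixed bandwidth
can be forced. Before log-ratios, densities are floored at $10^{-12}$ and
floored evaluations are flagged rather than silently plotted, so sparse
tails never contribute silent $\pm\infty$.

**Crooks curve.** `crooks_curve()` evaluates
$\frac{1}{\beta}\log\hat\rho^F(w)/\hat\rho^B(-w)$ on a grid spanning the
observed forward values. The reported curve is the mean over 1000
bootstrap replicates (forward and backward samples resampled
independently, both densities refitted per replicate) with a pointwise
99% percentile band; the plug-in estimate is also returned. The object
additionally marks a `well_sampled` region — grid points where both
plug-in densities exceed 0.5% of their peaks. Outside it the reverse
density at $-w$ is exponentially rarer than the forward density at $w$
(by the theorem itself, a factor $e^{-w}$), so log-ratio values there rest
on unsampled tails; slope summaries should be restricted to the
well-sampled region.

**Jarzynski estimate.** `jarzynski()` averages $e^{-\beta w}$ over the
forward samples and attaches a percentile bootstrap CI (resample size =
sample size, 1000 replicates, 99% level by default). The result is
flagged consistent when $e^{-\beta\Delta F}$ lies inside the interval,
the decision rule used throughout.

**Per-participant fitting.** `fit_participant()` reconstructs the
equilibrium from the 100-trial baseline: $\hat b$ is the sample mean, the
support defaults to $[\hat b - 90, \hat b + 90]$ (widened if responses
spill over; a data-range rule is available), and $\hat\beta$ maximizes the
equilibrium log-likelihood by bounded search on $\log\beta \in
[\log 0.01, \log 100]$. Estimates pinned at a bound are flagged with a
warning: zero-variance baselines pin at the upper bound, flat baselines
that avoid the target at the lower. The procedure is isolated behind this
one function so a different fitting scheme can replace it. Note the mean
identifies $\hat b$ only when the response range is roughly centred on
the bias, which holds for baseline blocks recorded at $\theta = 0$.

**Equilibration diagnostic.** `equilibration_check()` compares pooled
washout-plateau responses with the fitted equilibrium CDF via the
Kolmogorov–Smirnov distance (default threshold 0.1). It is a diagnostic,
not a test: plateau trials are serially dependent, so no p-value is
claimed.

## Numerical choices

* Free energies use adaptive quadrature (`stats::integrate`) with the
  support split around the energy extremum, so narrow high-$\beta$ wells
  cannot be missed; absolute tolerance $10^{-9}$.
* Equilibrium sampling inverts a trapezoid CDF on a 4096-point uniform
  grid refined by 1024 extra points around the well.
* Bootstrap resamples that collapse to one distinct value fall back to
  the original-sample bandwidth.
* All stochastic operations accept explicit seeds and are bit-for-bit
  reproducible; the pipeline derives stage seeds from one master seed and
  logs them.

## Limitations

* **Estimator power under strong adaptation.** A learner locked to the
  moving well is charged $\approx +1$ of driving error per protocol step,
  giving forward values near $+24$ per segment. Jarzynski's equality then
  holds only through exponentially rare negative-excursion trajectories,
  which a 20-sample mean never sees: the estimator's CI lies far below 1
  even though the theorem is true. Consistency checks based on
  $\langle e^{-\beta w}\rangle$ are therefore informative only in the
  low-dissipation regime ($\beta\,\langle w\rangle$ of order one). This is
  intrinsic to exponential-work estimators, not to this implementation.
  Consequently, on the well-adapted synthetic cohort the correct-model
  consistency rate is near zero, and the corresponding check in the test
  suite documents this expected failure rather than hiding it.
* **Percentile CI coverage.** At 20 cycles the 99% percentile bootstrap
  interval for $\langle e^{-w}\rangle$ under-covers slightly (the test
  suite measures a containment frequency a few points above 0.92 across
  200 replicate runs): runs whose forward works happen to be all positive
  produce intervals entirely below 1. BCa or studentized intervals would
  likely close part of the gap but are deliberately not the default, to
  keep the plain percentile convention.
* **Randomization control at high fitted precision.** For tightly
  tracking learners the fitted $\hat\beta$ is large, and exponentiating
  $-\hat\beta w$ makes bootstrap intervals span many orders of magnitude;
  the temporally randomized control is then "consistent" vacuously for a
  sizeable fraction of participants. The Mexican-hat control, which
  injects a systematic signed bias into the work values, discriminates
  sharply in the same regime.
* Where a design detail was genuinely open — the exact excursion angles,
  the Mexican-hat closed form, the per-participant support rule — it is
  implemented as an explicit, documented default behind a configurable
  switch rather than asserted as the only possible choice.

## Problem sizes used in the checks

Long-run checks simulate 1000 cycles (66,000 trials); finite-sample
behaviour uses the experimental scale of 20 cycles with 1000 bootstrap
replicates, replicated 100–200 times for frequency statements; sampler
correctness uses $2\times 10^5$ Metropolis steps and $10^5$ equilibrium
draws; the discrete 3-state oracle uses exact enumeration plus $10^5$
sampled paths.
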