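Package: fluctlearn
Title: Fluctuation Theorems for Sensorimotor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of trial-by-trial sensorimotor adaptation under
    cyclic visuomotor rotation protocols using the tools of stochastic
    thermodynamics. Models steady-state pointing behaviour as a truncated
    Boltzmann equilibrium over an exponential-quadratic sensorimotor loss,
    decomposes trajectories into externally driven (work-like) and
    internally generated (heat-like) error changes, and tests Crooks'
    fluctuation theorem and Jarzynski's equality on per-cycle driving-error
    samples via kernel density estimation with bootstrap confidence bands.
    Includes a Metropolis-Hastings learner as a synthetic-data generator,
    per-participant fitting of the equilibrium model from baseline trials,
    equilibration diagnostics, hysteresis summaries, and negative controls
    (mis-specified loss, temporally randomized responses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
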