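#' Default pipeline configuration
#'
#' Returns the default configuration list for [run_pipeline()], with the
#' standard study settings: exponential-quadratic energy, the 20-cycle /
#' 66-trial protocol with a 100-trial baseline and a 30-degree triangular
#' excursion, the Metropolis-Hastings learner (proposal scale 10 degrees, 3
#' steps per trial), 1000 bootstraps at the 99% level, and a simulated
#' cohort of 10 well-adapted participants (per-participant inverse
#' temperature drawn uniformly from [6, 12], bias from [-3, 3] degrees).
#'
#' @return Nested list with sections `energy`, `protocol`, `learner`,
#'   `cohort`, `estimators`, `controls`.
#' @export
default_config <- function() {
  list(
    energy = list(kind = "exp_quad", beta = 1, bias_deg = 0,
                  support_deg = c(-90, 90), sigma_deg = 4),
    protocol = list(theta_peak = 30, forward_length = 25L,
                    plateau_length = 8L, n_cycles = 20L,
                    baseline_length = 100L),
    learner = list(proposal_scale = 10, steps_per_trial = 3L,
                   init = "equilibrium"),
    cohort = list(n_participants = 10L, beta_range = c(6, 12),
                  bias_range = c(-3, 3),
                  proposal_scale = 5, steps_per_trial = 300L),
    estimators = list(n_boot = 1000L, level = 0.99,
                      bandwidth = "silverman", delta_F = 0),
    controls = list(mexican_hat_sigma = 4, mexican_hat_beta = 1,
                    randomize = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML configuration file and merges it over [default_config()]
#' (missing keys keep their defaults). Sections: `energy` (keys `kind`,
#' `beta`, `bias_deg`, `support_deg`, `sigma_deg`), `protocol`, `learner`,
#' `cohort`, `estimators`, `controls`.
#'
#' @param path Path to the YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (key in names(user)) {
    if (is.list(base[[key]]) && is.list(user[[key]]))
      base[[key]] <- merge_config(base[[key]], user[[key]])
    else base[[key]] <- user[[key]]
  }
  base
}

config_energy_model <- function(cfg) {
  e <- cfg$energy
  energy_model(kind = e$kind, beta = e$beta, bias = e$bias_deg,
               support = e$support_deg,
               sigma = if (identical(e$kind, "mexican_hat")) e$sigma_deg)
}

config_protocol <- function(cfg) {
  p <- cfg$protocol
  build_protocol(theta_peak = p$theta_peak,
                 forward_length = p$forward_length,
                 plateau_length = p$plateau_length,
                 n_cycles = p$n_cycles,
                 baseline_length = p$baseline_length,
                 forward_angles = p$forward_angles)
}

config_learner <- function(cfg) {
  l <- cfg$learner
  learner_config(proposal_scale = l$proposal_scale,
                 steps_per_trial = l$steps_per_trial,
                 init = l$init)
}

#' Simulate a cohort of learners
#'
#' Simulates `n_participants` Metropolis-Hastings learners through the
#' protocol, each with its own inverse temperature and bias drawn uniformly
#' from the configured ranges (emulating between-participant variability).
#' The cohort uses its own learner settings (default: proposal scale 5
#' degrees, 300 transitions per trial) so that high-precision participants
#' can track the moving target well enough to qualify as adapted; the
#' coarser package-default learner cannot stay captured by the
#' degree-scale energy well when the rotation steps several degrees per
#' trial.
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param seed Integer seed; participant seeds are derived from it.
#' @return List with `trials` (stacked `trial_data`), `participants`
#'   (data frame of the true per-participant `beta`, `bias`, `seed`),
#'   `protocol`.
#' @export
simulate_cohort <- function(cfg = default_config(), seed = 1) {
  protocol <- config_protocol(cfg)
  lcfg <- learner_config(
    proposal_scale = cfg$cohort$proposal_scale %||% cfg$learner$proposal_scale,
    steps_per_trial = cfg$cohort$steps_per_trial %||% cfg$learner$steps_per_trial,
    init = cfg$learner$init)
  n <- cfg$cohort$n_participants
  set.seed(seed)
  betas <- stats::runif(n, cfg$cohort$beta_range[1L], cfg$cohort$beta_range[2L])
  biases <- stats::runif(n, cfg$cohort$bias_range[1L], cfg$cohort$bias_range[2L])
  seeds <- sample.int(.Machine$integer.max - n, n)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    m <- energy_model(cfg$energy$kind, beta = betas[i], bias = biases[i],
                      support = cfg$energy$support_deg,
                      sigma = if (identical(cfg$energy$kind, "mexican_hat"))
                        cfg$energy$sigma_deg)
    runs[[i]] <- simulate_run(m, protocol, lcfg, seed = seeds[i],
                              participant_id = sprintf("S%02d", i))
  }
  trials <- do.call(rbind, lapply(runs, as.data.frame))
  class(trials) <- c("trial_data", "data.frame")
  list(trials = trials,
       participants = data.frame(
         participant_id = sprintf("S%02d", seq_len(n)),
         beta = betas, bias = biases, seed = seeds),
       protocol = protocol)
}

# Analyse one participant's trials under a given energy model: work samples,
# Crooks curve, Jarzynski estimate.
analyse_participant <- function(model, protocol, trials, est, seed) {
  work <- extract_work_samples(model, protocol, trials)
  list(work = work,
       crooks = crooks_curve(work, beta = model$beta, delta_F = est$delta_F,
                             n_boot = est$n_boot, level = est$level,
                             seed = seed),
       jarzynski = jarzynski(work, beta = model$beta, delta_F = est$delta_F,
                             n_boot = est$n_boot, level = est$level,
                             seed = seed + 1L))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis on a cohort of trial tables:
#' optionally simulate the cohort, fit each participant's equilibrium model
#' from the baseline block, check washout equilibration, extract per-cycle
#' driving-error samples, estimate the Crooks curve and the Jarzynski
#' equality with bootstrap intervals, compute hysteresis and adaptation
#' summaries, and run the two negative controls (mis-specified Mexican-hat
#' loss; temporally randomized responses). All stochastic stages derive
#' their seeds from `seed` and record them in the report.
#'
#' @param config Configuration list (see [default_config()]) or the path to
#'   a YAML file for [read_config()].
#' @param trials Optional observed `trial_data` table (one or more
#'   participants). When `NULL`, a cohort is simulated per the config.
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, CSV/JSON artifacts and a
#'   run log are written there.
#' @return An object of class `pipeline_report`: per-participant list
#'   `participants` (fit, equilibration, work, crooks, jarzynski,
#'   hysteresis, adaptation, controls), `summary` data frame, `protocol`,
#'   `config`, `seed`.
#' @export
run_pipeline <- function(config = default_config(), trials = NULL, seed = 1,
                         out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    merge_config(default_config(), config)
  protocol <- config_protocol(cfg)
  est <- cfg$estimators

  simulated <- is.null(trials)
  if (simulated) {
    cohort <- simulate_cohort(cfg, seed = seed)
    trials <- cohort$trials
  }
  trials <- check_trials(trials)
  ids <- unique(trials$participant_id)

  set.seed(seed + 1L)
  stage_seeds <- matrix(sample.int(.Machine$integer.max - 10L,
                                   4L * length(ids)), ncol = 4L)

  results <- vector("list", length(ids))
  names(results) <- ids
  for (i in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    baseline <- tr$response_deg[tr$block == "baseline"]
    fit <- fit_participant(baseline)
    eq <- equilibration_check(plateau_responses(tr, protocol), fit)
    main <- analyse_participant(fit$model, protocol, tr, est,
                                seed = stage_seeds[i, 1L])
    hyst <- hysteresis_table(tr, protocol)
    adapt <- adaptation_fraction(tr, protocol, bias = fit$bias_hat)

    mh_model <- energy_model("mexican_hat",
                             beta = cfg$controls$mexican_hat_beta,
                             bias = fit$bias_hat,
                             support = fit$support_hat,
                             sigma = cfg$controls$mexican_hat_sigma)
    mh <- analyse_participant(mh_model, protocol, tr, est,
                              seed = stage_seeds[i, 2L])
    rnd <- NULL
    if (isTRUE(cfg$controls$randomize)) {
      rtr <- randomized_control(tr, seed = stage_seeds[i, 3L])
      rnd <- analyse_participant(fit$model, protocol, rtr, est,
                                 seed = stage_seeds[i, 4L])
    }
    results[[i]] <- list(
      participant_id = ids[i], fit = fit, equilibration = eq,
      work = main$work, crooks = main$crooks, jarzynski = main$jarzynski,
      hysteresis = hyst, adaptation = adapt,
      controls = list(mexican_hat = mh, randomized = rnd))
  }

  summary <- data.frame(
    participant_id = ids,
    beta_hat = vapply(results, function(r) r$fit$beta_hat, numeric(1L)),
    bias_hat = vapply(results, function(r) r$fit$bias_hat, numeric(1L)),
    equilibration_ks = vapply(results,
                              function(r) r$equilibration$ks_distance,
                              numeric(1L)),
    adaptation = vapply(results, function(r) r$adaptation$fraction,
                        numeric(1L)),
    jarzynski = vapply(results, function(r) r$jarzynski$point_estimate,
                       numeric(1L)),
    ci_low = vapply(results, function(r) r$jarzynski$ci_low, numeric(1L)),
    ci_high = vapply(results, function(r) r$jarzynski$ci_high, numeric(1L)),
    consistent = vapply(results, function(r) r$jarzynski$consistent,
                        logical(1L)),
    consistent_mexican_hat = vapply(results,
      function(r) r$controls$mexican_hat$jarzynski$consistent, logical(1L)),
    consistent_randomized = vapply(results, function(r)
      if (is.null(r$controls$randomized)) NA
      else r$controls$randomized$jarzynski$consistent, logical(1L)),
    row.names = NULL)

  report <- structure(
    list(participants = results, summary = summary, protocol = protocol,
         trials = trials, config = cfg, seed = seed, simulated = simulated),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Fluctuation-theorem analysis pipeline (seed ", x$seed, ", ",
      nrow(x$summary), " participants",
      if (x$simulated) ", simulated cohort", ")\n\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

# Write the report bundle: trial CSV, work CSV, per-participant Crooks CSVs,
# summary CSV, JSON summary, run log.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(report$trials, file.path(out_dir, "trials.csv"))
  work_all <- do.call(rbind, lapply(report$participants, function(r)
    work_samples_table(r$work)))
  utils::write.csv(work_all, file.path(out_dir, "work_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  for (r in report$participants) {
    utils::write.csv(as.data.frame(r$crooks),
                     file.path(out_dir, paste0("crooks_",
                                               r$participant_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jz <- lapply(report$participants, function(r) list(
    point_estimate = r$jarzynski$point_estimate,
    ci = c(r$jarzynski$ci_low, r$jarzynski$ci_high),
    level = r$jarzynski$level,
    consistent = r$jarzynski$consistent,
    n_boot = r$jarzynski$n_boot,
    seed = r$jarzynski$seed))
  jsonlite::write_json(
    list(seed = report$seed,
         config_hash = config_hash(report$config),
         resampling = "forward and backward resampled independently",
         jarzynski = jz),
    file.path(out_dir, "jarzynski.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("fluctlearn pipeline run, seed ", report$seed),
    paste0("config hash: ", config_hash(report$config)),
    paste0("participants: ",
           paste(report$summary$participant_id, collapse = ", ")),
    paste0("simulated cohort: ", report$simulated))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small stable checksum without extra dependencies
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 257)) %% 1e9
}
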