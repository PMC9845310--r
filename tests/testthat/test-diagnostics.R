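test_that("trial tables round-trip through CSV", {
  m <- energy_model(beta = 1)
  p <- build_protocol(n_cycles = 2, baseline_length = 10)
  td <- simulate_run(m, p, learner_config(), seed = 61)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(td, path)
  back <- read_trials(path)
  expect_equal(back$theta_deg, round(td$theta_deg, 6))
  expect_equal(back$response_deg, round(td$response_deg, 6))
  expect_identical(back$participant_id, td$participant_id)
  expect_identical(back$block, td$block)
  # a second write of what was read is byte-identical (canonical form)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed trial files are rejected informatively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,block,cycle,trial_index,theta_deg", path)
  expect_error(read_trials(path), "response_deg")
  writeLines(c("participant_id,block,cycle,trial_index,theta_deg,response_deg",
               "S1,main,1,1,0,oops"), path)
  expect_error(read_trials(path), "non-numeric")
  writeLines("participant_id,block,cycle,trial_index,theta_deg,response_deg",
             path)
  expect_warning(empty <- read_trials(path), "no rows")
  expect_equal(nrow(empty), 0L)
})

test_that("perfect tracker shows zero hysteresis on any protocol", {
  set.seed(62)
  for (i in 1:5) {
    p <- build_protocol(theta_peak = stats::runif(1, 5, 45),
                        forward_length = sample(c(9, 17, 25), 1),
                        plateau_length = sample(2:8, 1),
                        n_cycles = sample(2:4, 1), baseline_length = 5)
    tracker <- fluctlearn:::trial_table(p, p$angles, "tracker")
    ht <- hysteresis_table(tracker, p)
    expect_equal(ht$forward_mean, ht$theta_deg, tolerance = 1e-12)
    expect_lt(max(abs(ht$difference)), 1e-12)
  }
})

test_that("one-trial-lag tracker reproduces the hysteresis sign pattern", {
  p <- build_protocol(n_cycles = 2, baseline_length = 5)
  lagged <- c(0, p$angles[-length(p$angles)])
  td <- fluctlearn:::trial_table(p, lagged, "lag")
  ht <- hysteresis_table(td, p)
  # ascending limbs: forward mean below backward mean; descending: above
  ascending1 <- 2:6     # rising toward +peak
  descending <- 9:17    # falling through zero to -peak
  ascending2 <- 21:24   # rising back to zero
  expect_true(all(ht$difference[ascending1] < 0))
  expect_true(all(ht$difference[descending] > 0))
  expect_true(all(ht$difference[ascending2] < 0))
})

test_that("adaptation fraction scores trackers, non-adapters and half-adapters", {
  p <- build_protocol(n_cycles = 2, baseline_length = 5)
  tracker <- fluctlearn:::trial_table(p, p$angles, "t")
  expect_equal(adaptation_fraction(tracker, p)$fraction, 1, tolerance = 1e-12)
  flat <- fluctlearn:::trial_table(p, rep(0, length(p$angles)), "f")
  af0 <- adaptation_fraction(flat, p)
  expect_equal(af0$fraction, 0)
  expect_false(af0$adapted)
  half <- fluctlearn:::trial_table(p, 0.5 * p$angles, "h")
  afh <- adaptation_fraction(half, p)
  expect_equal(afh$fraction, 0.5, tolerance = 1e-12)
  expect_true(afh$adapted)       # the criterion is inclusive
  # invariant under joint addition of a bias to responses and fit
  biased <- fluctlearn:::trial_table(p, 0.5 * p$angles + 7, "b")
  expect_equal(adaptation_fraction(biased, p, bias = 7)$fraction, 0.5,
               tolerance = 1e-12)
  p0 <- build_protocol(theta_peak = 0)
  expect_error(adaptation_fraction(tracker, p0), "undefined")
})

test_that("randomized control resamples within participants, reproducibly", {
  m <- energy_model(beta = 1)
  p <- build_protocol(n_cycles = 2, baseline_length = 10)
  td <- rbind(simulate_run(m, p, learner_config(), seed = 63,
                           participant_id = "A"),
              simulate_run(m, p, learner_config(), seed = 64,
                           participant_id = "B"))
  class(td) <- c("trial_data", "data.frame")
  r1 <- randomized_control(td, seed = 65)
  r2 <- randomized_control(td, seed = 65)
  expect_identical(r1$response_deg, r2$response_deg)
  for (id in c("A", "B")) {
    orig <- td$response_deg[td$participant_id == id & td$block == "main"]
    rand <- r1$response_deg[r1$participant_id == id & r1$block == "main"]
    expect_length(rand, length(orig))
    expect_true(all(rand %in% orig))
  }
  # baseline untouched, theta untouched
  expect_identical(r1$response_deg[r1$block == "baseline"],
                   td$response_deg[td$block == "baseline"])
  expect_identical(r1$theta_deg, td$theta_deg)
})

test_that("pipeline runs end to end, writes artifacts, and is deterministic", {
  cfg <- default_config()
  cfg$cohort$n_participants <- 2L
  cfg$cohort$steps_per_trial <- 20L    # small smoke cohort
  cfg$protocol$n_cycles <- 6L
  cfg$estimators$n_boot <- 50L
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(cfg, seed = 66, out_dir = out1))
  r2 <- suppressWarnings(run_pipeline(cfg, seed = 66, out_dir = out2))
  expect_s3_class(r1, "pipeline_report")
  expect_equal(nrow(r1$summary), 2L)
  for (f in c("trials.csv", "work_samples.csv", "summary.csv",
              "jarzynski.json", "run_log.txt", "crooks_S01.csv"))
    expect_true(file.exists(file.path(out1, f)))
  # same seeds -> byte-identical numeric outputs
  for (f in c("trials.csv", "work_samples.csv", "summary.csv",
              "crooks_S01.csv", "crooks_S02.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("YAML configuration merges over the defaults", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("energy:", "  beta: 2.5", "protocol:", "  n_cycles: 3"), path)
  cfg <- read_config(path)
  expect_equal(cfg$energy$beta, 2.5)
  expect_equal(cfg$protocol$n_cycles, 3)
  expect_equal(cfg$energy$kind, "exp_quad")        # untouched default
  expect_equal(cfg$estimators$n_boot, 1000L)
})
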