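required_trial_columns <- c("participant_id", "block", "cycle",
                            "trial_index", "theta_deg", "response_deg")

# Validate a trial table against the column contract; returns it with the
# trial_data class attached.
check_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("'trials' must be a data frame")
  missing_cols <- setdiff(required_trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("cycle", "trial_index", "theta_deg", "response_deg")) {
    if (!is.numeric(trials[[col]]))
      stop("column '", col, "' must be numeric")
  }
  if (nrow(trials)) {
    if (any(trials$trial_index < 1L)) stop("'trial_index' must be >= 1")
    if (!all(is.finite(trials$theta_deg)) ||
        !all(is.finite(trials$response_deg)))
      stop("'theta_deg' and 'response_deg' must be finite")
  }
  if (!inherits(trials, "trial_data"))
    class(trials) <- c("trial_data", class(trials))
  trials
}

#' Read a trial table from CSV
#'
#' Reads trial-level adaptation data in the canonical format: a
#' comma-separated, UTF-8, header-bearing file with columns
#' `participant_id`, `block` (`baseline`/`main`), `cycle` (0 for baseline),
#' `trial_index` (1-based within block/cycle), `theta_deg`, `response_deg`.
#' Unknown columns are preserved. Round-trips bit-exactly with
#' [write_trials()] for canonical files.
#'
#' @param path Path to the CSV file.
#' @return A `trial_data` data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(trials) == 0L) {
    warning("trial file '", path, "' contains a header but no rows")
    for (col in c("cycle", "trial_index", "theta_deg", "response_deg"))
      trials[[col]] <- numeric(0)
  }
  for (col in c("cycle", "trial_index", "theta_deg", "response_deg")) {
    if (!is.numeric(trials[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(trials[[col]]))) &
                     !is.na(trials[[col]]))
      stop("non-numeric value in column '", col, "' at data line ",
           if (length(bad)) bad[1L] else NA)
    }
  }
  check_trials(trials)
}

#' Write a trial table to CSV
#'
#' @param trials A `trial_data` data frame (see [read_trials()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- check_trials(trials)
  out <- as.data.frame(trials)
  for (col in c("theta_deg", "response_deg"))
    out[[col]] <- round(out[[col]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Hysteresis summary over forward/backward segments
#'
#' For each forward-segment position, the mean response across complete
#' cycles, together with the mean response at the *mirrored* backward
#' position (backward trial \eqn{L + 1 - k} sees the same true angle as
#' forward trial \eqn{k}, since the backward segment is the reversed
#' forward segment). A nonzero `difference` column at matched true angles
#' is the hysteresis signature of history-dependent adaptation.
#'
#' @param trials A single participant's `trial_data` table.
#' @param protocol The [build_protocol()] the data follow.
#' @return Data frame with columns `position`, `theta_deg`,
#'   `forward_mean`, `backward_mean`, `difference`
#'   (forward − backward).
#' @export
hysteresis_table <- function(trials, protocol) {
  stopifnot(is_protocol(protocol))
  trials <- check_trials(trials)
  main <- trials[trials$block == "main", , drop = FALSE]
  if (nrow(main) == 0L) stop("no main-block trials")
  L <- protocol$forward_range[2L] - protocol$forward_range[1L] + 1L
  complete <- vapply(unique(main$cycle), function(cy)
    sum(main$cycle == cy) == protocol$cycle_length, logical(1L))
  if (!all(complete)) {
    warning(sum(!complete), " incomplete cycle(s) skipped")
    main <- main[main$cycle %in% unique(main$cycle)[complete], , drop = FALSE]
  }
  if (nrow(main) == 0L) stop("no complete cycles")

  pos_mean <- function(idx_within_cycle) {
    vapply(idx_within_cycle, function(k)
      mean(main$response_deg[main$trial_index == k]), numeric(1L))
  }
  fwd_idx <- seq.int(protocol$forward_range[1L], protocol$forward_range[2L])
  bwd_idx <- seq.int(protocol$backward_range[2L], protocol$backward_range[1L])
  data.frame(
    position = seq_len(L),
    theta_deg = protocol$cycle_angles[fwd_idx],
    forward_mean = pos_mean(fwd_idx),
    backward_mean = pos_mean(bwd_idx),
    difference = pos_mean(fwd_idx) - pos_mean(bwd_idx)
  )
}

#' Adaptation fraction of a participant
#'
#' Summarizes how much of the imposed rotation a participant compensates:
#' the regression-through-origin slope of the (bias-corrected) mean forward
#' response on the imposed angle across forward-segment positions. A perfect
#' tracker scores 1, a non-adapter 0. Participants at or above 0.5 meet the
#' "at least 50% adaptation" inclusion criterion.
#'
#' @inheritParams hysteresis_table
#' @param bias Participant bias \eqn{\hat b} (degrees) subtracted from the
#'   responses before the fit.
#' @return List with `fraction` and `adapted` (`fraction >= 0.5`).
#' @export
adaptation_fraction <- function(trials, protocol, bias = 0) {
  stopifnot(is_protocol(protocol))
  if (protocol$theta_peak == 0)
    stop("adaptation fraction is undefined for an all-zero protocol ",
         "(theta_peak = 0)")
  ht <- hysteresis_table(trials, protocol)
  theta <- ht$theta_deg
  resp <- ht$forward_mean - bias
  fraction <- sum(theta * resp) / sum(theta^2)
  list(fraction = fraction, adapted = fraction >= 0.5)
}

#' Temporally randomized control
#'
#' Destroys the Markovian trial-to-trial structure while preserving each
#' participant's marginal response distribution: for every participant, the
#' main-block responses are replaced by an i.i.d. resample (with
#' replacement) of that participant's own main-block responses, re-assigned
#' across all main-block trials. The \eqn{\theta} sequence and baseline
#' block are untouched. Under this control the fluctuation-theorem
#' predictions should fail for adapted participants.
#'
#' @param trials A `trial_data` table (one or more participants).
#' @param seed Optional integer seed.
#' @return A `trial_data` table of the same shape.
#' @export
randomized_control <- function(trials, seed = NULL) {
  trials <- check_trials(trials)
  if (nrow(trials) == 0L) stop("'trials' is empty")
  if (!is.null(seed)) set.seed(seed)
  for (id in unique(trials$participant_id)) {
    sel <- trials$participant_id == id & trials$block == "main"
    obs <- trials$response_deg[sel]
    trials$response_deg[sel] <- sample(obs, length(obs), replace = TRUE)
  }
  trials
}

# Pooled washout-plateau responses of a single participant.
plateau_responses <- function(trials, protocol) {
  main <- trials[trials$block == "main", , drop = FALSE]
  main$response_deg[main$trial_index %in% plateau_index(protocol)]
}
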