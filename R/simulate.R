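#' Simulate one observer's session
#'
#' Runs a full session trial by trial: the stratified schedule fixes the cue
#' object, delay and gap side of each trial; boundary separation and
#' non-decision time are looked up by whole cue object; drift follows the
#' additive validity link at the current (titrated) gap. Choices and RTs are
#' first-passage samples of the diffusion process on the response-window
#' clock, censored at the window as non-responses. With probability
#' `guess_rate` a trial is replaced by a random-choice guess with uniform RT;
#' gaze contamination and keypress failures are independent per-trial
#' Bernoulli events. The staircase is updated every `window_trials` trials
#' from all trials run so far (before any exclusions), non-responses scoring
#' as incorrect.
#'
#' @param design A [design_spec()].
#' @param params A [observer_params()].
#' @param seed Integer seed; the session is a deterministic function of
#'   `(design, params, seed)`.
#' @param subject_id Subject label stored in the log.
#' @param titrate If `FALSE` the gap is held fixed at `params$gap_ref_deg`,
#'   which makes each cell's generating parameters exactly constant --
#'   the configuration used for parameter-recovery studies.
#' @return A data frame of trial records (one row per trial) with columns
#'   `subject_id`, `block_index`, `trial_index`, `cue_object`, `space_valid`,
#'   `feature_valid`, `delay_ms`, `gap_size_deg`, `gap_side`, `response`,
#'   `rt_s`, `gaze_contaminated`, `is_guess`.
#' @examples
#' log1 <- simulate_session(design_spec("E1"), observer_params(), seed = 1)
#' nrow(log1)  # 560
#' @export
simulate_session <- function(design, params, seed, subject_id = "S01",
                             titrate = TRUE) {
  stopifnot(inherits(design, "cue_design"), inherits(params, "cue_observer"))
  seeds <- derive_seeds(seed, 2)
  sched <- build_schedule(design, seeds[1])
  set.seed(seeds[2])
  n_total <- nrow(sched)
  window_s <- design$response_window_ms / 1000
  tspec <- design$titration
  w <- tspec$window_trials

  sv <- space_valid_of(sched$cue_object)
  fv <- feature_valid_of(sched$cue_object)
  a_t <- unname(params$a_by_object[sched$cue_object])
  ter_t <- unname(params$ter_by_object[sched$cue_object])

  gap <- if (titrate) tspec$gap_init_deg else params$gap_ref_deg
  gap_size <- numeric(n_total)
  response <- character(n_total)
  rt <- rep(NA_real_, n_total)
  is_guess <- logical(n_total)
  correct_all <- logical(n_total)  # titration bookkeeping, pre-exclusion

  done <- 0L
  while (done < n_total) {
    n_now <- min(w, n_total - done)
    idx <- done + seq_len(n_now)
    gap_size[idx] <- gap
    v <- drift_for_trial(params, sv[idx], fv[idx], gap)
    ddm <- sample_ddm_trials(n_now, v, a_t[idx], ter_t[idx], s = params$s,
                             max_rt_s = window_s)
    resp <- ifelse(ddm$responded,
                   ifelse(ddm$correct, sched$gap_side[idx],
                          ifelse(sched$gap_side[idx] == "left", "right", "left")),
                   "none")
    rts <- ddm$rt_s
    # fast-guess contamination: random choice, uniform RT over the window
    g <- stats::runif(n_now) < params$guess_rate
    if (any(g)) {
      resp[g] <- sample(c("left", "right"), sum(g), replace = TRUE)
      rts[g] <- stats::runif(sum(g), 0, window_s)
    }
    # keypress failure overrides everything else
    nr <- stats::runif(n_now) < params$nonresponse_rate
    resp[nr] <- "none"
    rts[nr] <- NA_real_
    response[idx] <- resp
    rt[idx] <- rts
    is_guess[idx] <- g & !nr
    correct_all[idx] <- resp == sched$gap_side[idx]  # "none" is incorrect
    done <- done + n_now
    if (titrate && n_now == w)
      gap <- titration_step(gap, correct_all[idx], tspec)
  }

  data.frame(subject_id = subject_id,
             block_index = (seq_len(n_total) - 1L) %/% design$trials_per_block,
             trial_index = seq_len(n_total) - 1L,
             cue_object = sched$cue_object,
             space_valid = sv, feature_valid = fv,
             delay_ms = sched$delay_ms,
             gap_size_deg = gap_size,
             gap_side = sched$gap_side,
             response = response,
             rt_s = rt,
             gaze_contaminated = stats::runif(n_total) < params$gaze_loss_rate,
             is_guess = is_guess,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of observers
#'
#' Each subject gets an independent sub-seed derived from the master seed,
#' so the cohort is reproducible as a whole and subjects are mutually
#' independent.
#'
#' @inheritParams simulate_session
#' @param n_subjects Number of observers.
#' @param seed Master seed.
#' @return Concatenated trial logs with distinct `subject_id` values.
#' @examples
#' log2 <- simulate_cohort(design_spec("E1"), observer_params(),
#'                         n_subjects = 2, seed = 7)
#' nrow(log2)  # 1120
#' @export
simulate_cohort <- function(design, params, n_subjects, seed,
                            titrate = TRUE) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(seed, n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  out <- lapply(seq_len(n_subjects), function(i)
    simulate_session(design, params, seed = seeds[i], subject_id = ids[i],
                     titrate = titrate))
  do.call(rbind, out)
}

#' Generic simulate method for synthetic observers
#'
#' `simulate()` on a [observer_params()] object draws `nsim` independent
#' subjects under the given design.
#'
#' @param object A `cue_observer`.
#' @param nsim Number of subjects.
#' @param seed Master seed.
#' @param design A [design_spec()].
#' @param ... Passed to [simulate_cohort()].
#' @return A cohort trial log.
#' @export
simulate.cue_observer <- function(object, nsim = 1, seed = 1,
                                  design = design_spec("E1"), ...) {
  simulate_cohort(design, object, n_subjects = nsim, seed = seed, ...)
}

.trial_log_version <- "# ezcue trial log v1"

#' Write / read a trial log as CSV
#'
#' The CSV carries a one-line version header comment ahead of the column
#' header; `read_trial_log()` refuses files without it and validates the
#' column schema.
#'
#' @param log A trial-log data frame.
#' @param path File path.
#' @return `read_trial_log()` returns the trial-log data frame.
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.trial_log_version, con)
  utils::write.csv(log, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, .trial_log_version))
    stop_ez("not an ezcue trial log (missing version header): ", path)
  log <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  need <- c("subject_id", "block_index", "trial_index", "cue_object",
            "space_valid", "feature_valid", "delay_ms", "gap_size_deg",
            "gap_side", "response", "rt_s", "gaze_contaminated")
  missing <- setdiff(need, names(log))
  if (length(missing))
    stop_ez("trial log lacks columns: ", paste(missing, collapse = ", "))
  log
}
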