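#' One titration (staircase) update
#'
#' Evaluates accuracy over the trailing window of trial outcomes and moves
#' the gap: above the band the gap shrinks by the step fraction, below it
#' the gap grows, inside the closed band it is unchanged. The result is
#' clamped to the gap bounds. Non-responses must already be coded `FALSE`
#' in `outcomes`.
#'
#' @param gap Current gap size (deg).
#' @param outcomes Logical vector of correct/incorrect for the trailing
#'   window (length `spec$window_trials`).
#' @param spec A [titration_spec()].
#' @return The updated gap size.
#' @examples
#' sp <- titration_spec()
#' titration_step(0.20, rep(c(TRUE, FALSE), c(12, 3)), sp)  # 0.8 acc -> 0.16
#' @export
titration_step <- function(gap, outcomes, spec) {
  stopifnot(inherits(spec, "titration_spec"))
  if (length(outcomes) == 0) stop_ez("empty titration window")
  if (length(outcomes) != spec$window_trials)
    stop_ez("titration_step expects exactly window_trials = ",
            spec$window_trials, " outcomes")
  acc <- mean(outcomes)
  if (acc > spec$band_high)
    max(gap * (1 - spec$step_fraction), spec$gap_min_deg)
  else if (acc < spec$band_low)
    min(gap * (1 + spec$step_fraction), spec$gap_max_deg)
  else gap
}

#' Run the titration staircase against an arbitrary observer
#'
#' Drives the staircase for `n_trials` trials. The observer is a function
#' `respond(gap, n)` returning `n` logical correctness values for trials at
#' the given gap; the gap is constant between evaluations, so the observer
#' is called once per window. A trailing partial window at the end of the
#' run is never evaluated.
#'
#' @param n_trials Number of trials to run.
#' @param respond Function `(gap, n) -> logical(n)`.
#' @param spec A [titration_spec()].
#' @param seed Optional seed for the observer's randomness.
#' @return A list with per-trial vectors `gap` (gap in effect) and
#'   `correct`, and `final_gap` (the gap after the last evaluation).
#' @examples
#' run <- titrate_run(600, function(gap, n) rep(TRUE, n), titration_spec())
#' run$final_gap  # clamped at the 0.05 deg floor
#' @export
titrate_run <- function(n_trials, respond, spec = titration_spec(),
                        seed = NULL) {
  stopifnot(inherits(spec, "titration_spec"), n_trials >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  gap <- spec$gap_init_deg
  gaps <- numeric(n_trials)
  correct <- logical(n_trials)
  done <- 0L
  w <- spec$window_trials
  while (done < n_trials) {
    n_now <- min(w, n_trials - done)
    idx <- done + seq_len(n_now)
    gaps[idx] <- gap
    correct[idx] <- respond(gap, n_now)
    done <- done + n_now
    if (n_now == w) gap <- titration_step(gap, correct[idx], spec)
  }
  list(gap = gaps, correct = correct, final_gap = gap)
}
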