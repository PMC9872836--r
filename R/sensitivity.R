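#' 2AFC sensitivity (d-prime)
#'
#' Computes `d' = z(H) - z(F)` for the two-alternative gap-side judgement,
#' treating "gap on the right edge" as the signal class: the hit rate is
#' the probability of a "right" response given a right-sided gap, the
#' false-alarm rate the probability of "right" given a left-sided gap.
#' The assignment is arbitrary and only fixes the sign convention; the
#' magnitude of d' is invariant to it.
#'
#' Extreme rates are handled by the log-linear correction (default): 0.5 is
#' added to all four response counts before rates are formed. The
#' alternative `"half_n"` correction replaces rates of 0 and 1 by `1/(2N)`
#' and `1 - 1/(2N)`; `"none"` rejects degenerate rates.
#'
#' @param n_right_given_right "Right" responses on right-gap trials.
#' @param n_right_given_left "Right" responses on left-gap trials.
#' @param n_right_trials,n_left_trials Trial counts per gap side (>= 1).
#' @param correction `"loglinear"` (default), `"half_n"` or `"none"`.
#' @return A list with `hit_rate`, `false_alarm_rate`, `d_prime`.
#' @examples
#' dprime_2afc(20, 0, 20, 20)$d_prime  # ~ 3.96 under log-linear correction
#' @export
dprime_2afc <- function(n_right_given_right, n_right_given_left,
                        n_right_trials, n_left_trials,
                        correction = c("loglinear", "half_n", "none")) {
  correction <- match.arg(correction)
  if (n_right_trials < 1 || n_left_trials < 1)
    stop_ez("need at least one trial of each gap side")
  if (n_right_given_right > n_right_trials ||
      n_right_given_left > n_left_trials)
    stop_ez("response counts exceed trial counts")
  if (correction == "loglinear") {
    H <- (n_right_given_right + 0.5) / (n_right_trials + 1)
    F <- (n_right_given_left + 0.5) / (n_left_trials + 1)
  } else {
    H <- n_right_given_right / n_right_trials
    F <- n_right_given_left / n_left_trials
    clamp <- function(p, n) {
      if (correction == "none") {
        if (p %in% c(0, 1))
          stop_ez("hit/false-alarm rate of 0 or 1 with correction = \"none\"")
        p
      } else min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    H <- clamp(H, n_right_trials)
    F <- clamp(F, n_left_trials)
  }
  list(hit_rate = H, false_alarm_rate = F,
       d_prime = stats::qnorm(H) - stats::qnorm(F))
}

#' Per-cell d-prime for a filtered trial log
#'
#' Computes [dprime_2afc()] for every subject-by-cue-object cell.
#'
#' @param trials A filtered trial log (no non-responses).
#' @param correction Passed to [dprime_2afc()].
#' @return A data frame with `subject_id`, `cue_object`, `hit_rate`,
#'   `false_alarm_rate`, `d_prime`.
#' @export
dprime_cells <- function(trials, correction = "loglinear") {
  if (any(trials$response == "none"))
    stop_ez("trials still contain non-responses; run apply_exclusions first")
  subjects <- sort(unique(trials$subject_id))
  grid <- expand.grid(subject_id = subjects, cue_object = CUE_OBJECTS,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- trials$subject_id == grid$subject_id[i] &
      trials$cue_object == grid$cue_object[i]
    d <- trials[sel, , drop = FALSE]
    nR <- sum(d$gap_side == "right")
    nL <- sum(d$gap_side == "left")
    if (nR < 1 || nL < 1)
      return(data.frame(subject_id = grid$subject_id[i],
                        cue_object = grid$cue_object[i],
                        hit_rate = NA_real_, false_alarm_rate = NA_real_,
                        d_prime = NA_real_, stringsAsFactors = FALSE))
    dp <- dprime_2afc(sum(d$gap_side == "right" & d$response == "right"),
                      sum(d$gap_side == "left" & d$response == "right"),
                      nR, nL, correction = correction)
    data.frame(subject_id = grid$subject_id[i],
               cue_object = grid$cue_object[i],
               hit_rate = dp$hit_rate, false_alarm_rate = dp$false_alarm_rate,
               d_prime = dp$d_prime, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
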