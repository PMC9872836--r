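#' Apply trial exclusions to a trial log
#'
#' Removes, in order: (1) practice-block trials; (2) gaze-contaminated
#' trials (blinks, saccades, fixations outside the fixation area, consumed
#' here as a per-trial flag); (3) trials with no designated keypress;
#' (4) optionally, trials -- correct and incorrect alike -- with RTs below
#' `fast_cutoff_s` (0.25 s reproduces the fast-response robustness check).
#' The report gives, for each stage, the count and the percentage of the
#' trials that entered that stage, mirroring how such exclusions are
#' conventionally reported.
#'
#' @param log A trial-log data frame (see [simulate_session()] for the
#'   schema).
#' @param fast_cutoff_s Optional fast-response cutoff in seconds
#'   (default `NULL`: stage disabled).
#' @param practice_blocks Number of leading blocks to drop (default 1).
#' @return A list with `trials` (the filtered log) and `report` (a data
#'   frame with columns `stage`, `n_in`, `n_removed`, `pct_removed`,
#'   `n_remaining`).
#' @export
apply_exclusions <- function(log, fast_cutoff_s = NULL, practice_blocks = 1L) {
  bad <- setdiff(unique(log$response), c("left", "right", "none"))
  if (length(bad))
    stop_ez("unknown response codes: ", paste(bad, collapse = ", "))
  stages <- list()
  note <- function(stage, keep, d) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_in = nrow(d), n_removed = sum(!keep),
      pct_removed = if (nrow(d)) 100 * mean(!keep) else 0,
      n_remaining = sum(keep))
    d[keep, , drop = FALSE]
  }
  d <- log
  d <- note("practice_block", d$block_index >= practice_blocks, d)
  d <- note("gaze_contaminated", !d$gaze_contaminated, d)
  d <- note("non_response", d$response != "none", d)
  if (!is.null(fast_cutoff_s))
    d <- note(sprintf("fast_rt_below_%gs", fast_cutoff_s),
              d$rt_s >= fast_cutoff_s, d)
  list(trials = d, report = do.call(rbind, stages))
}

#' Summarise condition cells for the EZ inversion
#'
#' Aggregates a filtered trial log into one cell per subject and cue object:
#' retained trial count, number correct, proportion correct, and the mean
#' and variance (n - 1 denominator) of correct-trial RTs. Subjects with
#' fewer than `min_correct` correct trials in any cell are flagged and, by
#' default, dropped from the returned table (generalising the exclusion of
#' subjects with a single correct trial in one condition).
#'
#' @param trials A filtered trial log (every row has a designated response
#'   and an RT).
#' @param min_correct Minimum correct trials per cell (default 2, the
#'   smallest count with a defined RT variance).
#' @param drop_subjects Drop flagged subjects from the output (default
#'   `TRUE`); they are always listed in the `dropped_subjects` attribute.
#' @return A data frame with columns `subject_id`, `cue_object`, `n_total`,
#'   `n_correct`, `Pc`, `MRT`, `VRT`, plus attribute `dropped_subjects`.
#' @export
summarize_cells <- function(trials, min_correct = 2, drop_subjects = TRUE) {
  if (nrow(trials) == 0) stop_ez("no trials to summarise")
  if (any(trials$response == "none"))
    stop_ez("trials still contain non-responses; run apply_exclusions first")
  correct <- trials$response == trials$gap_side
  subjects <- sort(unique(trials$subject_id))
  grid <- expand.grid(subject_id = subjects, cue_object = CUE_OBJECTS,
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- trials$subject_id == grid$subject_id[i] &
      trials$cue_object == grid$cue_object[i]
    rt_c <- trials$rt_s[sel & correct]
    data.frame(subject_id = grid$subject_id[i],
               cue_object = grid$cue_object[i],
               n_total = sum(sel),
               n_correct = length(rt_c),
               Pc = if (sum(sel)) mean(correct[sel]) else NA_real_,
               MRT = if (length(rt_c)) mean(rt_c) else NA_real_,
               VRT = if (length(rt_c) >= 2) stats::var(rt_c) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  low <- cells$n_correct < min_correct | cells$n_total == 0
  dropped <- unique(cells$subject_id[low])
  if (length(dropped))
    message("subjects with < ", min_correct,
            " correct trials in some cell: ", paste(dropped, collapse = ", "),
            if (drop_subjects) " (dropped)" else " (flagged)")
  if (drop_subjects) cells <- cells[!cells$subject_id %in% dropped, ,
                                    drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "dropped_subjects") <- dropped
  cells
}
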