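# Shared fixtures: oracle observers for the staircase and a hand-built
# trial-log constructor for preprocessing tests.

respond_always <- function(gap, n) rep(TRUE, n)

# deterministic 50% accuracy by alternation
respond_chance <- function(gap, n) rep(c(TRUE, FALSE), length.out = n)

# diffusion observer whose accuracy rises from ~55% at the gap floor to
# ~95% at the ceiling (drift proportional to gap)
respond_ddm <- function(gap, n) {
  v <- 0.026 * gap / 0.05
  x <- sample_ddm_trials(n, v, a = 0.1, ter = 0.25, s = 0.1, max_rt_s = 1.5)
  !is.na(x$correct) & x$correct
}

# minimal trial log with full schema; fields overridable per column
make_log <- function(n = 8, subject_id = "S01", block_index = 1L,
                     cue_object = "SvFv", gap_side = "right",
                     response = "right", rt_s = 0.5,
                     gaze_contaminated = FALSE, is_guess = FALSE) {
  data.frame(subject_id = subject_id,
             block_index = rep_len(block_index, n),
             trial_index = seq_len(n) - 1L,
             cue_object = rep_len(cue_object, n),
             space_valid = rep_len(cue_object, n) %in% c("SvFv", "SvFi"),
             feature_valid = rep_len(cue_object, n) %in% c("SvFv", "SiFv"),
             delay_ms = 1000,
             gap_size_deg = 0.2,
             gap_side = rep_len(gap_side, n),
             response = rep_len(response, n),
             rt_s = rep_len(rt_s, n),
             gaze_contaminated = rep_len(gaze_contaminated, n),
             is_guess = rep_len(is_guess, n),
             stringsAsFactors = FALSE)
}

# balanced synthetic log: each subject x cue object gets n_per trials with
# both gap sides, generated from the closed-form accuracy of the given
# observer at a fixed gap (no sequential structure) -- fast fixture for
# pipeline-level tests
make_cell_log <- function(n_subjects = 3, n_per = 40, params = observer_params(),
                          gap = params$gap_ref_deg, seed = 1) {
  set.seed(seed)
  cues <- c("SvFv", "SvFi", "SiFv", "SiFi")
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (co in cues) {
      v <- drift_for_trial(params, co %in% c("SvFv", "SvFi"),
                           co %in% c("SvFv", "SiFv"), gap)
      x <- sample_ddm_trials(n_per, v, params$a_by_object[[co]],
                             params$ter_by_object[[co]], s = params$s,
                             max_rt_s = 1.5)
      side <- rep(c("left", "right"), length.out = n_per)
      resp <- ifelse(is.na(x$correct), "none",
                     ifelse(x$correct, side,
                            ifelse(side == "left", "right", "left")))
      out[[length(out) + 1]] <- data.frame(
        subject_id = sprintf("S%02d", s), block_index = 1L,
        trial_index = seq_len(n_per) - 1L, cue_object = co,
        space_valid = co %in% c("SvFv", "SvFi"),
        feature_valid = co %in% c("SvFv", "SiFv"),
        delay_ms = 1000, gap_size_deg = gap, gap_side = side,
        response = resp, rt_s = x$rt_s,
        gaze_contaminated = FALSE, is_guess = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
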