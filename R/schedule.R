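#' Build a stratified trial schedule for one session
#'
#' Condition frequencies are assigned exactly (probability times total trial
#' count per cue object, which must be an integer), gap sides are balanced
#' 50/50 within each cue object up to rounding, cue-target delays are drawn
#' uniformly from the design's delay set, and the trial order is a seeded
#' shuffle of the whole session. There is therefore no sampling error in the
#' per-condition counts.
#'
#' @param design A [design_spec()].
#' @param seed Integer seed for the shuffle and delay draw.
#' @return A data frame with one row per trial and columns `cue_object`,
#'   `delay_ms`, `gap_side`.
#' @examples
#' sched <- build_schedule(design_spec("E1"), seed = 1)
#' table(sched$cue_object)  # exactly 392/56/56/56
#' @export
build_schedule <- function(design, seed) {
  stopifnot(inherits(design, "cue_design"))
  n_total <- design$n_blocks * design$trials_per_block
  counts <- design$cue_object_probs * n_total
  if (any(abs(counts - round(counts)) > 1e-9))
    stop_ez("cue-object probabilities times ", n_total,
            " trials do not give integer counts; refusing to round silently")
  counts <- as.integer(round(counts))

  set.seed(as.integer(seed))
  cue <- rep(CUE_OBJECTS, counts)
  side <- unlist(lapply(counts, function(k) {
    n_left <- k %/% 2L
    s <- c(rep("left", n_left), rep("right", k - n_left))
    # odd counts: the extra trial's side is randomized
    if (k %% 2L == 1L) s <- sample(s)
    s
  }), use.names = FALSE)
  delay <- sample(design$delays_ms, n_total, replace = TRUE)
  ord <- sample.int(n_total)
  data.frame(cue_object = cue[ord], delay_ms = delay,
             gap_side = side[ord], stringsAsFactors = FALSE)
}
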