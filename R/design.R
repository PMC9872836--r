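#' Titration (adaptive staircase) settings
#'
#' The gap in the target square is adjusted online to hold overall accuracy
#' inside a band. Accuracy pooled over all cue types is evaluated every
#' `window_trials` trials over the trailing window; when it exceeds
#' `band_high` the gap shrinks by `step_fraction`, when it falls below
#' `band_low` the gap grows by `step_fraction`, always clamped to
#' `[gap_min_deg, gap_max_deg]`. Non-responses count as incorrect.
#'
#' @param gap_min_deg Minimum gap size, visual degrees.
#' @param gap_max_deg Maximum gap size, visual degrees.
#' @param gap_init_deg Starting gap size; defaults to the maximum, matching
#'   the early-session dynamics in which the gap first approaches the ceiling
#'   while the observer learns the task.
#' @param step_fraction Multiplicative step (0.2 = 20 percent).
#' @param window_trials Number of trials between evaluations.
#' @param band_low,band_high Target accuracy band (proportions correct).
#'   Accuracy inside the closed band leaves the gap unchanged.
#' @return An object of class `titration_spec`.
#' @export
titration_spec <- function(gap_min_deg = 0.05, gap_max_deg = 0.5,
                           gap_init_deg = gap_max_deg,
                           step_fraction = 0.20, window_trials = 15L,
                           band_low = 0.60, band_high = 0.70) {
  if (!(gap_min_deg > 0 && gap_min_deg < gap_max_deg))
    stop_ez("need 0 < gap_min_deg < gap_max_deg")
  if (gap_init_deg < gap_min_deg || gap_init_deg > gap_max_deg)
    stop_ez("gap_init_deg must lie in [gap_min_deg, gap_max_deg]")
  if (step_fraction <= 0 || step_fraction >= 1)
    stop_ez("step_fraction must be in (0, 1)")
  if (window_trials < 1) stop_ez("window_trials must be >= 1")
  if (!(band_low < band_high && band_low >= 0 && band_high <= 1))
    stop_ez("need 0 <= band_low < band_high <= 1")
  structure(list(gap_min_deg = gap_min_deg, gap_max_deg = gap_max_deg,
                 gap_init_deg = gap_init_deg, step_fraction = step_fraction,
                 window_trials = as.integer(window_trials),
                 band_low = band_low, band_high = band_high),
            class = "titration_spec")
}

# Cue-object probabilities of the three dual-cue designs, order SvFv, SvFi,
# SiFv, SiFi. E1: the whole cue is valid on most trials. E2a: each component
# is solely valid on 40% of trials. E2b: the feature component is the more
# reliable one (80% valid in total) while spatial validity stays at 50%.
.design_probs <- list(
  E1  = c(SvFv = 0.70, SvFi = 0.10, SiFv = 0.10, SiFi = 0.10),
  E2a = c(SvFv = 0.10, SvFi = 0.40, SiFv = 0.40, SiFi = 0.10),
  E2b = c(SvFv = 0.40, SvFi = 0.10, SiFv = 0.40, SiFi = 0.10))

#' Specify a dual-cue visual search design
#'
#' A design bundles the cue-object probabilities, block structure, cue-target
#' delays, response window and titration settings of one experiment. The
#' three built-in designs (`"E1"`, `"E2a"`, `"E2b"`) share 7 blocks of 80
#' trials (first block = practice), delays of 500/1000/1500 ms and a 1500 ms
#' response window; they differ only in how often each cue object (SvFv,
#' SvFi, SiFv, SiFi -- spatial/feature component valid or invalid) occurs.
#'
#' @param experiment_id `"E1"`, `"E2a"` or `"E2b"`.
#' @param cue_object_probs Named numeric vector of probabilities for
#'   SvFv/SvFi/SiFv/SiFi; defaults to the built-in design's values.
#' @param n_blocks,trials_per_block,practice_blocks Block structure.
#' @param delays_ms Possible cue-to-target delays (ms), sampled uniformly.
#' @param response_window_ms Response window from mask onset (ms).
#' @param titration A [titration_spec()].
#' @return An object of class `cue_design`.
#' @examples
#' design_spec("E1")
#' @export
design_spec <- function(experiment_id = c("E1", "E2a", "E2b"),
                        cue_object_probs = NULL,
                        n_blocks = 7L, trials_per_block = 80L,
                        practice_blocks = 1L,
                        delays_ms = c(500, 1000, 1500),
                        response_window_ms = 1500,
                        titration = titration_spec()) {
  experiment_id <- match.arg(experiment_id)
  probs <- cue_object_probs %||% .design_probs[[experiment_id]]
  if (is.null(names(probs)) || !setequal(names(probs), CUE_OBJECTS))
    stop_ez("cue_object_probs must be named with ", paste(CUE_OBJECTS, collapse = ", "))
  probs <- probs[CUE_OBJECTS]
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop_ez("cue_object_probs must be >= 0 and sum to 1")
  if (n_blocks < 1 || trials_per_block < 1 || practice_blocks < 0 ||
      practice_blocks >= n_blocks)
    stop_ez("invalid block structure")
  if (!inherits(titration, "titration_spec"))
    stop_ez("titration must be a titration_spec object")
  structure(list(experiment_id = experiment_id,
                 cue_object_probs = probs,
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 practice_blocks = as.integer(practice_blocks),
                 delays_ms = as.numeric(delays_ms),
                 response_window_ms = as.numeric(response_window_ms),
                 titration = titration),
            class = "cue_design")
}

#' @export
print.cue_design <- function(x, ...) {
  cat("Dual-cue search design", x$experiment_id, "\n")
  cat(sprintf("  %d blocks x %d trials (%d practice), %d trials total\n",
              x$n_blocks, x$trials_per_block, x$practice_blocks,
              x$n_blocks * x$trials_per_block))
  cat("  cue-object probabilities:",
      paste(sprintf("%s=%.2f", names(x$cue_object_probs), x$cue_object_probs),
            collapse = " "), "\n")
  cat("  delays (ms):", paste(x$delays_ms, collapse = ", "),
      " response window (ms):", x$response_window_ms, "\n")
  invisible(x)
}

# Per-experiment contamination rates observed in comparable human cohorts:
# proportion of trials lost to blinks/saccades/fixation breaks, and the
# proportion with no designated keypress.
.contamination_defaults <- list(
  E1  = list(gaze = 0.1549, nonresp = 0.0075),
  E2a = list(gaze = 0.1120, nonresp = 0.0137),
  E2b = list(gaze = 0.1070, nonresp = 0.0098))

#' Generative observer parameters
#'
#' Parameters of the synthetic observer: a diffusion process whose drift is
#' additive in the validity of the spatial and feature cue components and
#' proportional to the current gap size, while boundary separation and
#' non-decision time depend on the whole cue object (its overall
#' probability), plus contamination processes (gaze loss, non-responses,
#' fast uniform guesses).
#'
#' Default drift parameters reproduce marginal drift means of 0.13 for a
#' valid and 0.087 for an invalid cue component (either dimension) at the
#' reference gap; default boundaries and non-decision times reproduce the
#' high-probability-cue pattern (largest `a` and shortest `ter` for SvFv)
#' with marginal means near a = 0.080/0.071 (feature valid/invalid) and
#' ter = 0.23/0.26.
#'
#' @param s Diffusion noise scale (dimensionless). The conventional 0.1.
#' @param v_base Baseline drift for a wholly invalid cue at the reference gap.
#' @param dv_space,dv_feature Additive drift increments for a valid spatial /
#'   feature cue component.
#' @param gap_ref_deg Reference gap size (deg) at which the drift parameters
#'   are stated; drift scales as `gap / gap_ref_deg`.
#' @param a_by_object Named vector: boundary separation per cue object.
#' @param ter_by_object Named vector: non-decision time (s) per cue object.
#' @param guess_rate Probability a trial is replaced by a uniform-RT,
#'   random-choice guess.
#' @param gaze_loss_rate Probability a trial is flagged gaze-contaminated.
#' @param nonresponse_rate Probability of no designated keypress.
#' @param experiment_id Optional; picks gaze/non-response defaults matching
#'   that experiment's observed contamination levels.
#' @return An object of class `cue_observer`.
#' @examples
#' observer_params()
#' @export
observer_params <- function(s = 0.1,
                            v_base = 0.0655,
                            dv_space = 0.043, dv_feature = 0.043,
                            gap_ref_deg = 0.2,
                            a_by_object = c(SvFv = 0.085, SvFi = 0.069,
                                            SiFv = 0.075, SiFi = 0.072),
                            ter_by_object = c(SvFv = 0.21, SvFi = 0.25,
                                              SiFv = 0.25, SiFi = 0.27),
                            guess_rate = 0.02,
                            gaze_loss_rate = NULL,
                            nonresponse_rate = NULL,
                            experiment_id = "E1") {
  cd <- .contamination_defaults[[experiment_id]] %||%
    list(gaze = 0.12, nonresp = 0.01)
  gaze_loss_rate <- gaze_loss_rate %||% cd$gaze
  nonresponse_rate <- nonresponse_rate %||% cd$nonresp
  if (s <= 0) stop_ez("s must be > 0")
  if (gap_ref_deg <= 0) stop_ez("gap_ref_deg must be > 0")
  for (nm in c("a_by_object", "ter_by_object")) {
    v <- get(nm)
    if (is.null(names(v)) || !setequal(names(v), CUE_OBJECTS))
      stop_ez(nm, " must be named with ", paste(CUE_OBJECTS, collapse = ", "))
  }
  a_by_object <- a_by_object[CUE_OBJECTS]
  ter_by_object <- ter_by_object[CUE_OBJECTS]
  if (any(a_by_object <= 0)) stop_ez("all boundary separations must be > 0")
  if (any(ter_by_object < 0)) stop_ez("all non-decision times must be >= 0")
  rates <- c(guess_rate, gaze_loss_rate, nonresponse_rate)
  if (any(rates < 0 | rates > 1)) stop_ez("rates must lie in [0, 1]")
  if (v_base <= 0) stop_ez("v_base must be > 0")
  structure(list(s = s, v_base = v_base, dv_space = dv_space,
                 dv_feature = dv_feature, gap_ref_deg = gap_ref_deg,
                 a_by_object = a_by_object, ter_by_object = ter_by_object,
                 guess_rate = guess_rate, gaze_loss_rate = gaze_loss_rate,
                 nonresponse_rate = nonresponse_rate),
            class = "cue_observer")
}

#' @export
print.cue_observer <- function(x, ...) {
  cat("Synthetic dual-cue observer (diffusion)\n")
  cat(sprintf("  drift: v_base=%.4f + Sv*%.4f + Fv*%.4f, scaled by gap/%.2f deg; s=%.2f\n",
              x$v_base, x$dv_space, x$dv_feature, x$gap_ref_deg, x$s))
  cat("  a by cue object:  ",
      paste(sprintf("%s=%.3f", names(x$a_by_object), x$a_by_object), collapse = " "), "\n")
  cat("  ter by cue object:",
      paste(sprintf("%s=%.2f", names(x$ter_by_object), x$ter_by_object), collapse = " "), "\n")
  cat(sprintf("  contamination: gaze %.1f%%, non-response %.1f%%, guesses %.1f%%\n",
              100 * x$gaze_loss_rate, 100 * x$nonresponse_rate, 100 * x$guess_rate))
  invisible(x)
}
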