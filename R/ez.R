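#' EZ-diffusion forward equations
#'
#' Closed-form accuracy and correct-RT moments of the unbiased diffusion
#' model (start point `a/2`, no across-trial variability). With
#' `y = -v * a / s^2`:
#' \deqn{P_c = 1/(1+e^y)}
#' \deqn{MDT = (a/(2v)) (1-e^y)/(1+e^y)}
#' \deqn{VRT = (a s^2/(2 v^3)) (2 y e^y - e^{2y} + 1)/(e^y+1)^2}
#' and `MRT = MDT + ter`. At `v -> 0` the analytic limits are used:
#' `Pc = 1/2`, `MDT = a^2/(4 s^2)`, `VRT = a^4/(24 s^4)`.
#'
#' @param v Drift rate (may be 0).
#' @param a Boundary separation, > 0.
#' @param ter Non-decision time (s).
#' @param s Noise scale (default 0.1).
#' @return A list with `Pc`, `MRT`, `VRT` (vectorised over the inputs).
#' @examples
#' ez_forward(0.1, 0.14, 0.3)
#' @export
ez_forward <- function(v, a, ter, s = 0.1) {
  if (any(a <= 0) || any(s <= 0)) stop_ez("need a > 0 and s > 0")
  n <- max(length(v), length(a), length(ter))
  v <- rep_len(v, n); a <- rep_len(a, n); ter <- rep_len(ter, n)
  y <- -v * a / s^2
  small <- abs(y) < 1e-5   # series limit; avoids catastrophic cancellation
  Pc <- ifelse(small, 0.5, 1 / (1 + exp(y)))
  mdt <- ifelse(small, a^2 / (4 * s^2),
                (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y)))
  vrt <- ifelse(small, a^4 / (24 * s^4),
                (a * s^2 / (2 * v^3)) *
                  (2 * y * exp(y) - exp(2 * y) + 1) / (exp(y) + 1)^2)
  list(Pc = Pc, MRT = mdt + ter, VRT = vrt)
}

#' EZ-diffusion inversion
#'
#' Recovers drift rate, boundary separation and non-decision time from
#' accuracy and the mean and variance of correct RTs, by the exact algebraic
#' inversion of [ez_forward()]: `L = logit(Pc)`,
#' `x = L (L Pc^2 - L Pc + Pc - 1/2) / VRT`, `v = sign(Pc - 1/2) s x^{1/4}`,
#' `a = s^2 L / v`, `ter = MRT - MDT`.
#'
#' Accuracies of exactly 0, 1/2 or 1 have no finite preimage; they are
#' replaced by `1/(2n)`, `1/2 + 1/(2n)` and `1 - 1/(2n)` respectively
#' (edge correction `"half_n"`, requiring the cell's trial count `n`),
#' with a warning.
#'
#' @param Pc Proportion correct.
#' @param MRT Mean correct RT (s).
#' @param VRT Variance of correct RT (s^2), > 0.
#' @param n Trial count behind `Pc`; needed only when an edge correction
#'   fires.
#' @param s Noise scale (default 0.1).
#' @param edge_correction `"half_n"` (default) or `"none"` (degenerate
#'   accuracies are an error).
#' @return A list with estimates `v`, `a`, `ter` and diagnostics `mdt`
#'   (mean decision time), `L` (logit accuracy), `y` (`-v a / s^2`),
#'   `corrected` (logical).
#' @examples
#' f <- ez_forward(0.1, 0.14, 0.3)
#' ez_inverse(f$Pc, f$MRT, f$VRT)   # recovers 0.1, 0.14, 0.3
#' @export
ez_inverse <- function(Pc, MRT, VRT, n = NULL, s = 0.1,
                       edge_correction = c("half_n", "none")) {
  edge_correction <- match.arg(edge_correction)
  if (any(VRT <= 0)) stop_ez("VRT must be > 0")
  if (any(Pc < 0 | Pc > 1)) stop_ez("Pc must lie in [0, 1]")
  len <- max(length(Pc), length(MRT), length(VRT))
  Pc <- rep_len(Pc, len); MRT <- rep_len(MRT, len); VRT <- rep_len(VRT, len)
  degenerate <- Pc == 0 | Pc == 0.5 | Pc == 1
  corrected <- degenerate
  if (any(degenerate)) {
    if (edge_correction == "none")
      stop_ez("Pc of 0, 1/2 or 1 cannot be inverted without an edge correction")
    if (is.null(n))
      stop_ez("edge correction requires the cell trial count n")
    n <- rep_len(n, len)
    repl <- ifelse(Pc == 0, 1 / (2 * n),
            ifelse(Pc == 1, 1 - 1 / (2 * n), 0.5 + 1 / (2 * n)))
    warning(sprintf("%d accuracy value(s) at 0, 1/2 or 1 replaced by a 1/(2n) edge correction",
                    sum(degenerate)), call. = FALSE)
    Pc[degenerate] <- repl[degenerate]
  }
  L <- stats::qlogis(Pc)
  x <- L * (L * Pc^2 - L * Pc + Pc - 0.5) / VRT
  v <- sign(Pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  list(v = v, a = a, ter = MRT - mdt, mdt = mdt, L = L, y = y,
       corrected = corrected)
}

#' Fit the EZ-diffusion model to condition cells
#'
#' Applies [ez_inverse()] to each subject-by-cue-object cell produced by
#' [summarize_cells()]. Cells with fewer than `min_n` retained trials are
#' flagged and their estimates set to `NA` so they drop out of group-level
#' statistics.
#'
#' @param cells A data frame of condition cells (columns `subject_id`,
#'   `cue_object`, `n_total`, `n_correct`, `Pc`, `MRT`, `VRT`).
#' @param s Noise scale.
#' @param min_n Minimum retained trials for a cell to be estimated.
#' @param edge_correction Passed to [ez_inverse()].
#' @return `cells` augmented with columns `v`, `a`, `ter`, `corrected`,
#'   `low_n`.
#' @export
ez_fit_cells <- function(cells, s = 0.1, min_n = 10,
                         edge_correction = "half_n") {
  need <- c("subject_id", "cue_object", "n_total", "Pc", "MRT", "VRT")
  if (!all(need %in% names(cells)))
    stop_ez("cells must have columns ", paste(need, collapse = ", "))
  out <- cells
  out$v <- out$a <- out$ter <- NA_real_
  out$corrected <- FALSE
  out$low_n <- cells$n_total < min_n
  ok <- !out$low_n & is.finite(cells$VRT) & cells$VRT > 0
  if (any(ok)) {
    est <- ez_inverse(cells$Pc[ok], cells$MRT[ok], cells$VRT[ok],
                      n = cells$n_total[ok], s = s,
                      edge_correction = edge_correction)
    out$v[ok] <- est$v
    out$a[ok] <- est$a
    out$ter[ok] <- est$ter
    out$corrected[ok] <- est$corrected
  }
  out
}
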