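#' Drift rate for one trial
#'
#' The generative drift is exactly additive in the validity of the two cue
#' components and proportional to the current gap size:
#' `v = (v_base + Sv * dv_space + Fv * dv_feature) * gap / gap_ref`.
#' There is no interaction term, so drift differences between feature-valid
#' and feature-invalid cue objects are identical at both levels of spatial
#' validity (and vice versa).
#'
#' @param params A [observer_params()].
#' @param space_valid,feature_valid Logical (vectorised).
#' @param gap_size_deg Gap size(s), visual degrees, > 0.
#' @return Numeric drift rate(s).
#' @export
drift_for_trial <- function(params, space_valid, feature_valid, gap_size_deg) {
  stopifnot(inherits(params, "cue_observer"))
  if (any(gap_size_deg <= 0)) stop_ez("gap_size_deg must be > 0")
  v <- (params$v_base + space_valid * params$dv_space +
          feature_valid * params$dv_feature) * gap_size_deg / params$gap_ref_deg
  if (any(v <= 0))
    stop_ez("observer configuration yields non-positive drift; ",
            "check v_base, dv_space and dv_feature")
  v
}

#' Sample first-passage outcomes of an unbiased diffusion process
#'
#' Evidence starts at `a/2` and diffuses with drift `v` and infinitesimal
#' standard deviation `s` between absorbing boundaries at 0 and `a`; hitting
#' the upper boundary is a correct response. Integration is Euler-Maruyama
#' with a Brownian-bridge correction for within-step boundary crossings,
#' which removes the order-sqrt(dt) first-passage bias of the plain scheme.
#' The returned RT is `ter` plus the decision time; decision times that
#' would push the RT past `max_rt_s` are censored as non-responses.
#'
#' @param n Number of trials to sample.
#' @param v,a,ter Drift, boundary separation, non-decision time (s); scalars
#'   or length-`n` vectors.
#' @param s Diffusion noise scale.
#' @param dt Integration step (s), at most 0.001.
#' @param max_rt_s Censoring point on the RT clock (response window), or
#'   `Inf` for the uncensored process.
#' @return A data frame with logical `correct`, numeric `rt_s` (NA when
#'   censored) and logical `responded`.
#' @examples
#' set.seed(1)
#' x <- sample_ddm_trials(1000, v = 0.1, a = 0.14, ter = 0.3)
#' mean(x$correct)
#' @export
sample_ddm_trials <- function(n, v, a, ter, s = 0.1, dt = 0.001,
                              max_rt_s = Inf) {
  if (!all(is.finite(c(v, a, ter, s))) || any(a <= 0) || any(s <= 0) ||
      any(ter < 0))
    stop_ez("parameters must be finite with a > 0, s > 0, ter >= 0")
  if (dt > 0.001 || dt <= 0) stop_ez("dt must be in (0, 0.001]")
  n <- as.integer(n)
  v <- rep_len(v, n); a <- rep_len(a, n); ter <- rep_len(ter, n)
  # decision-time budget per trial given the RT censoring point
  t_budget <- pmax(max_rt_s - ter, 0)
  x <- a / 2
  t_dec <- rep(NA_real_, n)
  correct <- rep(NA, n)
  active <- t_budget > 0
  sd_step <- s * sqrt(dt)
  k <- 0L
  max_steps <- if (is.finite(max_rt_s)) ceiling(max(t_budget) / dt)
               else ceiling(60 / dt)  # hard cap for the uncensored process
  while (any(active) && k < max_steps) {
    k <- k + 1L
    idx <- which(active)
    x0 <- x[idx]
    x1 <- x0 + v[idx] * dt + stats::rnorm(length(idx), 0, sd_step)
    ai <- a[idx]
    up <- x1 >= ai
    lo <- x1 <= 0
    inside <- !(up | lo)
    if (any(inside)) {
      # Brownian-bridge probability of an unobserved within-step crossing
      p_up <- exp(-2 * (ai[inside] - x0[inside]) * (ai[inside] - x1[inside]) /
                    (s^2 * dt))
      p_lo <- exp(-2 * x0[inside] * x1[inside] / (s^2 * dt))
      u <- stats::runif(sum(inside))
      bridge_up <- u < p_up
      bridge_lo <- !bridge_up & (u < p_up + p_lo)
      up[inside] <- bridge_up
      lo[inside] <- lo[inside] | bridge_lo
    }
    done <- up | lo
    if (any(done)) {
      di <- idx[done]
      hit_time <- k * dt
      ok <- hit_time <= t_budget[di]
      t_dec[di[ok]] <- hit_time
      correct[di[ok]] <- up[done][ok]
      active[di] <- FALSE   # censored trials also stop here
    }
    x[idx] <- x1
    # trials whose budget expires this step become non-responses
    expired <- active & (k * dt >= t_budget)
    active[expired] <- FALSE
  }
  responded <- !is.na(t_dec)
  data.frame(correct = ifelse(responded, correct, NA),
             rt_s = ter + t_dec, responded = responded)
}

#' Sample a single diffusion trial
#'
#' Scalar convenience wrapper around [sample_ddm_trials()].
#'
#' @inheritParams sample_ddm_trials
#' @param response_window_s Response window (s) on the RT clock.
#' @param seed Optional seed.
#' @return A list with `choice` (`"correct"`, `"error"` or `"none"`) and
#'   `rt_s` (NA for `"none"`).
#' @export
sample_ddm_trial <- function(v, a, ter, s = 0.1, response_window_s = Inf,
                             dt = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- sample_ddm_trials(1L, v, a, ter, s = s, dt = dt,
                         max_rt_s = response_window_s)
  if (!x$responded) list(choice = "none", rt_s = NA_real_)
  else list(choice = if (isTRUE(x$correct)) "correct" else "error",
            rt_s = x$rt_s)
}
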