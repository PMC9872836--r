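---
title: "Simulating and decomposing dual-cue visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decomposing dual-cue visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezcue)
```

## The problem

In dual-cue visual search, a single central pre-cue carries two pieces of
information at once: an arrow's *direction* predicts where the target will
appear (spatial attention) and its *colour* predicts what the target will
look like (feature-based attention). Each component can be valid or invalid
on a given trial, giving four cue objects — SvFv, SvFi, SiFv, SiFi — whose
relative frequencies define an experiment. The observer's task is a
two-alternative forced choice: report whether a small gap in the target
square sits on its left or right edge, within a 1500 ms response window.

A central question in this paradigm is *where* in the processing stream the
two attention systems interact. Accuracy and RT alone cannot separate a
sharper sensory signal from a more cautious response policy or a faster
attentional set-up. The EZ-diffusion decomposition does: it maps a
condition's accuracy (`Pc`), mean correct RT (`MRT`) and variance of correct
RT (`VRT`) onto the three parameters of an unbiased diffusion process —
drift rate `v` (evidence quality), boundary separation `a` (response
caution) and non-decision time `ter` (everything outside accumulation).

This package provides the full chain — synthetic experiment generation,
trial exclusion, 2AFC sensitivity, EZ decomposition and the inferential
layer — so that every stage can be validated by parameter recovery on data
whose ground truth is known.

## The generative model

`observer_params()` defines a synthetic observer:

* **Drift.** `v = (v_base + Sv*dv_space + Fv*dv_feature) * gap/gap_ref`.
  The two validity increments are exactly additive (no interaction term),
  encoding the hypothesis that spatial and feature selection independently
  improve signal quality; drift grows linearly with the titrated gap size,
  which is the minimal monotone link between difficulty and evidence.
* **Boundary and non-decision time** are looked up by *whole cue object*,
  not by component validity. This encodes the complementary hypothesis that
  response caution and preparatory time track the probability of the whole
  cueing object: in the default (E1-like) parameters the most frequent cue,
  SvFv, gets the widest boundary (0.085) and the shortest non-decision time
  (0.21 s).
* **Diffusion noise** uses the conventional scale `s = 0.1`, which puts
  drift in the 0.02–0.3 range, boundaries near 0.07–0.09 and non-decision
  times near 0.2–0.35 s.

The default drift parameters (`v_base = 0.0655`, increments `0.043`) are
chosen so the marginal means at the reference gap are 0.13 for a valid and
0.087 for an invalid cue component on either dimension. The default `a` and
`ter` tables reproduce the corresponding marginal means to within rounding;
the four published marginals of a 2x2 table over-determine its cells, so the
feature marginals are matched exactly and the spatial ones to ~0.001 (`a`)
and ~0.01 (`ter`).

Contamination has three independent channels, matching how real sessions
degrade: gaze loss (blinks/saccades; a per-trial Bernoulli flag, default
rates 15.5%/11.2%/10.7% for E1/E2a/E2b), keypress failures (~1%), and fast
uniform guesses (default 2%). The generator does *not* emulate sequential
effects, fatigue drifts, or gaze dynamics within a trial — so passing
recovery tests show the estimator chain is sound, not that real data meet
its assumptions.

## Designs and the titration staircase

`design_spec()` carries the three built-in designs (560 trials = 7 blocks of
80, the first block practice; delays 500/1000/1500 ms):

| design | SvFv | SvFi | SiFv | SiFi |
|--------|------|------|------|------|
| E1     | 70%  | 10%  | 10%  | 10%  |
| E2a    | 10%  | 40%  | 40%  | 10%  |
| E2b    | 40%  | 10%  | 40%  | 10%  |

Schedules are stratified exactly — probabilities times 560 must be integers,
and are for all three designs — so condition-frequency tests carry no
sampling error; non-integer stratifications are rejected rather than
silently rounded. Gap sides are balanced 50/50 within cue object; delays are
sampled uniformly (whether the original procedure balanced them is unstated;
uniform sampling is the weaker assumption).

The gap size is titrated to hold overall accuracy in the 60–70% band:
accuracy pooled over all cue types is evaluated every 15 trials, and the gap
shrinks or grows by 20% (clamped to 0.05°–0.5°) when accuracy leaves the
band. Two readings were open: we use a *trailing* 15-trial window (the
natural online implementation) and score non-responses as incorrect. The
starting gap is the 0.5° maximum, consistent with the gap approaching
ceiling during early practice. Titration operates on all trials before any
exclusion, matching how such staircases run online during acquisition.

Under an always-correct observer the staircase walks down to the 0.05°
floor and holds; under a chance observer it rises to the 0.5° ceiling. With
a calibrated diffusion observer whose accuracy spans roughly 55% at the
floor to 95% at the ceiling (`v = 0.026 * gap/0.05`, `a = 0.1`), long-run
titrated accuracy settles near 62%, inside the band. These three behaviours
are the package's staircase benchmarks (see `scripts/acceptance.R`).

## Preprocessing and condition cells

`apply_exclusions()` removes, in order: practice-block trials,
gaze-contaminated trials, non-responses, and (optionally) trials faster than
a cutoff — 0.25 s reproduces the fast-response robustness check; the filter
applies to correct and error trials alike since nothing distinguishes them
mechanistically. Every stage reports the percentage of trials entering it
that it removed, and the report reconciles exactly with the rows dropped.

`summarize_cells()` builds one cell per subject and cue object with `Pc`,
`MRT` and `VRT` over correct trials only, using the unbiased n−1 variance.
Subjects with fewer than 2 correct trials in any cell are dropped by
default (a cell needs two correct RTs for a defined variance); the threshold
is configurable.

## Sensitivity and the EZ decomposition

`dprime_2afc()` treats "gap on the right edge" as the signal class —
an arbitrary, documented convention that only fixes the sign. The default
log-linear correction adds 0.5 to all four counts, so perfect cells remain
finite; a `1/(2N)` clamp is available, and `correction = "none"` rejects
degenerate rates.

`ez_forward()` and `ez_inverse()` implement the closed-form mapping and its
exact algebraic inversion; round trips are exact to double precision over
the plausible parameter box (checked to 1e-8 relative error over
`v ∈ [0.02, 0.3]`, `a ∈ [0.05, 0.15]`, `ter ∈ [0.1, 0.4]`). Numerical
choices worth knowing:

* At `|v·a/s²| < 1e-5` the forward model switches to the analytic limits
  `Pc = 1/2`, `MDT = a²/(4s²)`, `VRT = a⁴/(24s⁴)`, avoiding catastrophic
  cancellation.
* Accuracies of exactly 0, 1/2 or 1 have no finite preimage and are
  replaced by `1/(2n)`-style corrections, always with a warning and a
  `corrected` flag.
* "Robust" fitting is realised as contaminant exclusion before inversion
  (gaze, non-response, optional fast cutoff), the variant that needs no
  extra degrees of freedom; a full guessing-mixture estimator is a possible
  extension, not implemented.

The trial sampler used everywhere (`sample_ddm_trials()`) integrates the
diffusion with Euler–Maruyama at `dt = 1` ms plus a Brownian-bridge
correction for within-step boundary crossings. The bridge term matters: it
removes the order-`sqrt(dt)` first-passage bias that a plain Euler scheme
carries at this step size, and the sampler is validated against the
closed-form moments at 3 Monte-Carlo standard errors across a grid of
parameter values (for `VRT` the SE uses the fourth central moment, since
correct-RT distributions are right-skewed and the normal-theory formula
understates the variance of a sample variance).

## Inference

`rm_anova_2x2()` computes the fully-within 2x2 ANOVA from within-subject
sums of squares (each effect: 1 and n−1 df; both factors have two levels so
no sphericity correction exists to make). Generalized eta squared uses the
fully-within formulation — effect SS over effect SS plus all subject-related
error SS. An effect with zero SS is reported as F = 0 rather than 0/0.
`paired_t()` adds Cohen's `dz = t/sqrt(n)` and a JZS Bayes factor with
Cauchy scale 0.707, computed by quadrature of the Zellner–Siow g-prior
integral under the substitution `g = r²z` so the prior mass stays
well-scaled for any prior width; it matches an independent noncentral-t
marginal quadrature to better than 1e-4 relative error and tends to 1 as
the prior scale shrinks. `within_subject_sem()` implements
Cousineau normalization with the Morey `sqrt(k/(k−1))` correction.

## Parameter recovery: what it shows

`cmd_recover()` simulates cohorts with the gap pinned at the reference size
and contamination off, so each cell's generating `(v, a, ter)` is exactly
constant, then runs the full pipeline. With 31 subjects and the E1 design
(480 analysed trials each), grand-mean recovery per parameter is within a
few percent, and the fitted cohort reproduces the generating structure: two
additive main effects and no interaction in drift, and the
SvFv-favouring pattern in boundary and non-decision time.

Two honest caveats. First, the E1 design gives the three rare cue objects
only 56 trials each before exclusions; at that size the EZ drift estimate
carries a positive small-sample bias of roughly +5 to +10% (a Jensen effect:
`v` is a convex function of the noisy `VRT`), visible in `cmd_recover()`'s
per-cell table. Second, under titration the gap — and with it the generating
drift — varies across the session, while the EZ cell model assumes
stationarity; fits to titrated sessions therefore estimate an effective,
session-averaged drift. Both are properties of the estimator, not bugs, and
both are reasons the recovery benchmark fixes the gap.

Problem sizes used by the validation suite — 50,000 trials per grid point
for the moment checks, 5,000 titrated trials for the staircase benchmark,
three replicate 31-subject cohorts for recovery — were chosen as the
smallest sizes at which the Monte-Carlo error is comfortably below each
criterion's tolerance.

## Known limitations

* The EZ decomposition assumes an unbiased start point, no across-trial
  parameter variability and, in its plain form, no contaminants; it cannot
  recover the seven-parameter diffusion model's variability parameters.
* ANOVA-level inclusion Bayes factors over mixed model spaces are out of
  scope; only paired-contrast JZS factors are provided.
* The simulator's contamination is exchangeable across trials; real gaze
  loss clusters in time.
* Cross-experiment (mixed-design) comparisons are not implemented.
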