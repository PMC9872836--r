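Package: ezcue
Title: Simulation and EZ-Diffusion Analysis of Dual-Cue Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing two-alternative forced-choice
    visual search experiments in which a single pre-cue carries both a spatial
    and a feature (colour) component. Provides a trial-level generator for
    dual-cue designs with stratified cue-object schedules, an adaptive
    gap-size titration staircase, and diffusion-model response generation;
    a preprocessing pipeline applying gaze, non-response and fast-response
    exclusions; 2AFC sensitivity (d-prime); a closed-form EZ-diffusion
    decomposition of accuracy and response-time moments into drift rate,
    boundary separation and non-decision time; and an inferential layer with
    2x2 repeated-measures ANOVA (generalized eta squared), paired t-tests
    with Cohen's dz and JZS Bayes factors, and within-participant standard
    errors. The central entry point is ez_fit(), which returns a fitted-model
    object with the usual print, summary, coef, predict and plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
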