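#' Read a run configuration
#'
#' Declarative YAML configuration for the end-to-end pipeline. Recognised
#' keys: `experiment` ("E1"/"E2a"/"E2b"), `n_subjects`, `seed`, `titrate`,
#' `observer` (a mapping of [observer_params()] arguments), `input_csv`
#' (an existing trial log to analyse instead of simulating), and
#' `preprocess` with `fast_cutoff_s` and `min_correct`. Exactly one of a
#' simulation block (`experiment`/`n_subjects`) or `input_csv` must drive
#' `cmd_analyze()`.
#'
#' @param config A YAML file path or an already-constructed list.
#' @return A validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_ez("config must be a list or a YAML file path")
  config$experiment <- config$experiment %||% "E1"
  config$n_subjects <- config$n_subjects %||% 31L
  config$seed <- config$seed %||% 1L
  config$titrate <- config$titrate %||% TRUE
  config$preprocess <- config$preprocess %||% list()
  if (is.null(config$input_csv) && is.null(config$experiment))
    stop_ez("config needs either a simulation block or input_csv")
  config
}

.config_observer <- function(config) {
  args <- config$observer %||% list()
  args$experiment_id <- args$experiment_id %||% config$experiment
  do.call(observer_params, args)
}

#' Simulate a cohort from a configuration and write its outputs
#'
#' Writes the cohort trial log, a schedule audit (realised cue-object
#' frequencies against the design's nominal percentages) and each subject's
#' gap-size titration trajectory.
#'
#' @param config Configuration (list or YAML path); see [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with the trial log and file paths.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- design_spec(config$experiment)
  params <- .config_observer(config)
  log <- simulate_cohort(design, params, config$n_subjects, config$seed,
                         titrate = isTRUE(config$titrate))
  paths <- list(trial_log = file.path(out_dir, "trial_log.csv"),
                audit = file.path(out_dir, "schedule_audit.csv"),
                titration = file.path(out_dir, "titration_trace.csv"))
  write_trial_log(log, paths$trial_log)
  counts <- table(log$subject_id, log$cue_object)[, CUE_OBJECTS, drop = FALSE]
  audit <- data.frame(cue_object = CUE_OBJECTS,
                      nominal_pct = 100 * unname(design$cue_object_probs),
                      realised_pct = 100 * colSums(counts) / sum(counts),
                      n_trials = colSums(counts))
  utils::write.csv(audit, paths$audit, row.names = FALSE)
  utils::write.csv(log[, c("subject_id", "trial_index", "gap_size_deg")],
                   paths$titration, row.names = FALSE)
  message("simulated ", config$n_subjects, " subjects x ",
          nrow(log) / config$n_subjects, " trials (", config$experiment, ")")
  invisible(list(log = log, paths = paths, design = design, params = params))
}

#' Analyse a trial log end to end
#'
#' Runs exclusions, condition-cell summaries, d-prime, the EZ-diffusion
#' inversion and the inferential layer, writing tidy CSVs: the exclusion
#' report, condition cells, per-cell d-prime and EZ estimates, per-measure
#' condition means with within-participant SEMs, and the effect table
#' (ANOVA F, df, p, generalized eta squared per measure).
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the `ez_fit` object and file paths.
#' @export
cmd_analyze <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$input_csv)) {
    log <- read_trial_log(config$input_csv)
  } else {
    log <- simulate_cohort(design_spec(config$experiment),
                           .config_observer(config),
                           config$n_subjects, config$seed,
                           titrate = isTRUE(config$titrate))
  }
  pp <- config$preprocess
  fit <- ez_fit(log, fast_cutoff_s = pp$fast_cutoff_s,
                min_correct = pp$min_correct %||% 2)
  s <- summary(fit)
  paths <- list(exclusions = file.path(out_dir, "exclusion_report.csv"),
                cells = file.path(out_dir, "condition_cells.csv"),
                dprime = file.path(out_dir, "dprime.csv"),
                estimates = file.path(out_dir, "ez_estimates.csv"),
                effects = file.path(out_dir, "effects.csv"),
                means = file.path(out_dir, "condition_means.csv"))
  utils::write.csv(fit$exclusions, paths$exclusions, row.names = FALSE)
  utils::write.csv(fit$cells, paths$cells, row.names = FALSE)
  utils::write.csv(fit$dprime, paths$dprime, row.names = FALSE)
  utils::write.csv(fit$estimates, paths$estimates, row.names = FALSE)
  effects <- do.call(rbind, lapply(names(s$anovas), function(m)
    cbind(measure = m, s$anovas[[m]])))
  utils::write.csv(effects, paths$effects, row.names = FALSE)
  means <- do.call(rbind, lapply(names(s$sems), function(m)
    cbind(measure = m, s$sems[[m]])))
  utils::write.csv(means, paths$means, row.names = FALSE)
  for (i in seq_len(nrow(fit$exclusions)))
    message(sprintf("exclusion stage %-22s removed %5d (%5.2f%%), %d remain",
                    fit$exclusions$stage[i], fit$exclusions$n_removed[i],
                    fit$exclusions$pct_removed[i],
                    fit$exclusions$n_remaining[i]))
  invisible(list(fit = fit, paths = paths))
}

#' Parameter-recovery study
#'
#' Simulates cohorts with known generating parameters (gap fixed at the
#' reference size so each cell's drift, boundary and non-decision time are
#' exactly constant), runs the full analysis pipeline and tabulates
#' generating versus recovered group means with bias and RMSE across
#' replicate seeds.
#'
#' @inheritParams cmd_simulate
#' @param n_seeds Number of replicate cohorts.
#' @param contaminate Keep the contamination processes on (default `FALSE`:
#'   recovery of the decision machinery itself).
#' @return Invisibly, the recovery table (also written to
#'   `recovery.csv` when `out_dir` is given).
#' @export
cmd_recover <- function(config, out_dir = NULL, seed = NULL, n_seeds = 1,
                        contaminate = FALSE) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  design <- design_spec(config$experiment)
  params <- .config_observer(config)
  if (!contaminate) {
    params$guess_rate <- 0
    params$gaze_loss_rate <- 0
    params$nonresponse_rate <- 0
  }
  truth <- data.frame(
    cue_object = CUE_OBJECTS,
    v = drift_for_trial(params, space_valid_of(CUE_OBJECTS),
                        feature_valid_of(CUE_OBJECTS), params$gap_ref_deg),
    a = unname(params$a_by_object),
    ter = unname(params$ter_by_object))
  seeds <- derive_seeds(config$seed, n_seeds)
  if (config$n_subjects < 4)
    warning("recovery with very few subjects is unreliable", call. = FALSE)
  rec <- lapply(seeds, function(sd) {
    log <- simulate_cohort(design, params, config$n_subjects, sd,
                           titrate = FALSE)
    fit <- ez_fit(log)
    gm <- .group_means(fit)
    gm[CUE_OBJECTS, c("v", "a", "ter")]
  })
  arr <- simplify2array(rec)  # cue x param x seed
  recovered <- apply(arr, c(1, 2), mean)
  out <- do.call(rbind, lapply(c("v", "a", "ter"), function(p) {
    data.frame(parameter = p, cue_object = CUE_OBJECTS,
               generating = truth[[p]],
               recovered = recovered[, p],
               bias_pct = 100 * (recovered[, p] - truth[[p]]) / truth[[p]],
               rmse = sapply(seq_along(CUE_OBJECTS), function(i)
                 sqrt(mean((arr[i, p, ] - truth[[p]][i])^2))))
  }))
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}
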