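#' Fit the EZ-diffusion decomposition to a dual-cue trial log
#'
#' The main modelling entry point. Applies the exclusion pipeline
#' ([apply_exclusions()]), aggregates subject-by-cue-object condition cells
#' ([summarize_cells()]), computes 2AFC sensitivity per cell
#' ([dprime_cells()]) and inverts the EZ-diffusion equations per cell
#' ([ez_fit_cells()]), returning a fitted-model object.
#'
#' @param trials A trial-log data frame or a path to a trial-log CSV
#'   written by [write_trial_log()].
#' @param fast_cutoff_s Optional fast-response exclusion cutoff (s).
#' @param practice_blocks Leading blocks to drop.
#' @param min_correct Minimum correct trials per cell before a subject is
#'   dropped.
#' @param min_n Minimum retained trials for a cell's EZ estimate.
#' @param s Diffusion noise scale.
#' @param edge_correction Edge correction for degenerate accuracies
#'   (see [ez_inverse()]).
#' @param dprime_correction Correction for extreme hit/false-alarm rates
#'   (see [dprime_2afc()]).
#' @return An object of class `ez_fit` with components `cells`,
#'   `estimates`, `dprime`, `exclusions`, `dropped_subjects`, `s`, `call`.
#' @examples
#' log1 <- simulate_cohort(design_spec("E1"), observer_params(),
#'                         n_subjects = 4, seed = 1)
#' fit <- ez_fit(log1)
#' coef(fit)[1:3, ]
#' summary(fit)
#' @export
ez_fit <- function(trials, fast_cutoff_s = NULL, practice_blocks = 1L,
                   min_correct = 2, min_n = 10, s = 0.1,
                   edge_correction = "half_n",
                   dprime_correction = "loglinear") {
  cl <- match.call()
  if (is.character(trials)) trials <- read_trial_log(trials)
  if (nrow(trials) == 0) stop_ez("empty trial log")
  excl <- apply_exclusions(trials, fast_cutoff_s = fast_cutoff_s,
                           practice_blocks = practice_blocks)
  cells <- summarize_cells(excl$trials, min_correct = min_correct)
  if (nrow(cells) == 0)
    stop_ez("no analysable subjects after exclusions")
  keep <- !excl$trials$subject_id %in% attr(cells, "dropped_subjects")
  analysed <- excl$trials[keep, , drop = FALSE]
  est <- ez_fit_cells(cells, s = s, min_n = min_n,
                      edge_correction = edge_correction)
  dp <- dprime_cells(analysed, correction = dprime_correction)
  structure(list(cells = cells, estimates = est, dprime = dp,
                 exclusions = excl$report,
                 dropped_subjects = attr(cells, "dropped_subjects"),
                 s = s, call = cl),
            class = "ez_fit")
}

#' @export
print.ez_fit <- function(x, ...) {
  n_subj <- length(unique(x$estimates$subject_id))
  cat("EZ-diffusion fit:", n_subj, "subjects x",
      length(CUE_OBJECTS), "cue objects\n")
  cat("Trials analysed:", sum(x$cells$n_total), "\n")
  if (length(x$dropped_subjects))
    cat("Dropped subjects:", paste(x$dropped_subjects, collapse = ", "), "\n")
  gm <- .group_means(x)
  print(round(gm, 3))
  invisible(x)
}

.group_means <- function(x) {
  est <- x$estimates
  dp <- x$dprime
  out <- sapply(CUE_OBJECTS, function(co) c(
    d_prime = mean(dp$d_prime[dp$cue_object == co], na.rm = TRUE),
    v = mean(est$v[est$cue_object == co], na.rm = TRUE),
    a = mean(est$a[est$cue_object == co], na.rm = TRUE),
    ter = mean(est$ter[est$cue_object == co], na.rm = TRUE)))
  t(out)
}

#' Extract per-subject EZ estimates
#'
#' @param object An `ez_fit`.
#' @param ... Unused.
#' @return Data frame of per-cell estimates: `subject_id`, `cue_object`,
#'   `v`, `a`, `ter`.
#' @export
coef.ez_fit <- function(object, ...) {
  object$estimates[, c("subject_id", "cue_object", "v", "a", "ter")]
}

#' Fitted accuracy and RT moments implied by the EZ estimates
#'
#' Pushes each cell's estimates back through the forward equations. Because
#' the EZ model is exactly identified, fitted moments equal the observed
#' ones except in cells where an edge correction fired.
#'
#' @param object An `ez_fit`.
#' @param ... Unused.
#' @return Data frame with observed and fitted `Pc`, `MRT`, `VRT` per cell.
#' @export
predict.ez_fit <- function(object, ...) {
  est <- object$estimates
  ok <- !is.na(est$v)
  fit <- data.frame(Pc_hat = NA_real_, MRT_hat = NA_real_,
                    VRT_hat = NA_real_)[rep(1, nrow(est)), ]
  if (any(ok)) {
    f <- ez_forward(est$v[ok], est$a[ok], est$ter[ok], s = object$s)
    fit$Pc_hat[ok] <- f$Pc
    fit$MRT_hat[ok] <- f$MRT
    fit$VRT_hat[ok] <- f$VRT
  }
  out <- cbind(est[, c("subject_id", "cue_object", "Pc", "MRT", "VRT")], fit)
  rownames(out) <- NULL
  out
}

#' @export
residuals.ez_fit <- function(object, ...) {
  p <- predict(object)
  data.frame(p[, c("subject_id", "cue_object")],
             Pc = p$Pc - p$Pc_hat, MRT = p$MRT - p$MRT_hat,
             VRT = p$VRT - p$VRT_hat)
}

#' Summarise an EZ-diffusion fit
#'
#' Group-level condition means with within-participant standard errors and
#' the 2x2 repeated-measures ANOVA (validity of the spatial cue x validity
#' of the feature cue) for sensitivity and each diffusion component.
#'
#' @param object An `ez_fit`.
#' @param ... Unused.
#' @return An object of class `summary.ez_fit`.
#' @export
summary.ez_fit <- function(object, ...) {
  measures <- list(d_prime = object$dprime[, c("subject_id", "cue_object", "d_prime")],
                   v = object$estimates[, c("subject_id", "cue_object", "v")],
                   a = object$estimates[, c("subject_id", "cue_object", "a")],
                   ter = object$estimates[, c("subject_id", "cue_object", "ter")])
  anovas <- list(); sems <- list()
  for (m in names(measures)) {
    d <- measures[[m]]
    names(d)[3] <- "value"
    d <- d[!is.na(d$value), , drop = FALSE]
    complete <- names(which(table(d$subject_id) == length(CUE_OBJECTS)))
    d <- d[d$subject_id %in% complete, , drop = FALSE]
    if (length(complete) >= 2) {
      anovas[[m]] <- rm_anova_2x2(d, "value")
      sems[[m]] <- within_subject_sem(d, "value")
    }
  }
  structure(list(group_means = .group_means(object), anovas = anovas,
                 sems = sems, exclusions = object$exclusions,
                 n_subjects = length(unique(object$estimates$subject_id))),
            class = "summary.ez_fit")
}

#' @export
print.summary.ez_fit <- function(x, ...) {
  cat("EZ-diffusion decomposition,", x$n_subjects, "subjects\n\n")
  cat("Group means per cue object:\n")
  print(round(x$group_means, 3))
  for (m in names(x$anovas)) {
    cat("\n2x2 repeated-measures ANOVA on", m, ":\n")
    a <- x$anovas[[m]]
    a$F <- round(a$F, 2); a$p <- signif(a$p, 3); a$eta_g2 <- round(a$eta_g2, 3)
    print(a, row.names = FALSE)
  }
  cat("\nExclusion report:\n")
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}

#' Plot condition means with within-participant error bars
#'
#' One panel per measure (d', v, a, ter): cue-object means with +/- 1
#' within-participant SEM, valid/invalid spatial cue on the x axis, filled
#' and open points for feature-valid and feature-invalid cues.
#'
#' @param x An `ez_fit`.
#' @param measures Character subset of `c("d_prime", "v", "a", "ter")`.
#' @param ... Unused.
#' @export
plot.ez_fit <- function(x, measures = c("d_prime", "v", "a", "ter"), ...) {
  s <- summary(x)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(d_prime = "sensitivity (d')", v = "drift rate v",
            a = "boundary separation a", ter = "non-decision time (s)")
  for (m in intersect(measures, names(s$sems))) {
    sem <- s$sems[[m]]
    sem <- sem[match(CUE_OBJECTS, sem$condition), ]
    xpos <- c(1, 1, 2, 2) + c(-0.05, 0.05, -0.05, 0.05)
    ylim <- range(sem$mean - sem$sem, sem$mean + sem$sem)
    graphics::plot(xpos, sem$mean, pch = c(16, 1, 16, 1), xlim = c(0.5, 2.5),
                   ylim = ylim + c(-1, 1) * 0.1 * diff(ylim),
                   xaxt = "n", xlab = "spatial cue", ylab = labs[m])
    graphics::axis(1, at = c(1, 2), labels = c("valid", "invalid"))
    graphics::arrows(xpos, sem$mean - sem$sem, xpos, sem$mean + sem$sem,
                     angle = 90, code = 3, length = 0.03)
    graphics::legend("topright", pch = c(16, 1), bty = "n", cex = 0.8,
                     legend = c("feature valid", "feature invalid"))
  }
  invisible(x)
}
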