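#' 2x2 repeated-measures ANOVA with generalized eta squared
#'
#' Classical fully-within two-factor ANOVA on one observation per subject
#' and cell, computed from within-subject sums of squares. For the 2x2
#' design each effect has 1 numerator df and `n - 1` denominator df, and no
#' sphericity correction is needed. Generalized eta squared uses the
#' fully-within formulation: `SS_effect / (SS_effect + SS_subjects +
#' SS_error_space + SS_error_feature + SS_error_interaction)`.
#'
#' An effect whose sum of squares is numerically zero (e.g. identical cells
#' for every subject) is reported as `F = 0`, `p = 1`.
#'
#' @param data Data frame with one row per subject and cue object.
#' @param value_col Name of the response column.
#' @param subject_col,cue_col Column names identifying subject and cue
#'   object (the latter coded SvFv/SvFi/SiFv/SiFi).
#' @return A data frame with rows `space`, `feature`, `interaction` and
#'   columns `effect`, `F`, `df1`, `df2`, `p`, `eta_g2`.
#' @export
rm_anova_2x2 <- function(data, value_col, subject_col = "subject_id",
                         cue_col = "cue_object") {
  y <- .cell_matrix(data, value_col, subject_col, cue_col)
  n <- nrow(y)
  if (n < 2) stop_ez("need at least two subjects")
  # factor coding per cue object column
  svf <- space_valid_of(colnames(y))
  fvf <- feature_valid_of(colnames(y))
  gm <- mean(y)
  sm <- rowMeans(y)
  # marginal means over the two levels of each factor, per subject
  s_v <- rowMeans(y[, svf, drop = FALSE]); s_i <- rowMeans(y[, !svf, drop = FALSE])
  f_v <- rowMeans(y[, fvf, drop = FALSE]); f_i <- rowMeans(y[, !fvf, drop = FALSE])
  SS_subj <- 4 * sum((sm - gm)^2)
  SS_s <- 2 * n * sum((c(mean(s_v), mean(s_i)) - gm)^2)
  SS_f <- 2 * n * sum((c(mean(f_v), mean(f_i)) - gm)^2)
  cellm <- colMeans(y)
  # interaction SS from cell means minus additive fit
  fit <- ifelse(svf, mean(s_v), mean(s_i)) + ifelse(fvf, mean(f_v), mean(f_i)) - gm
  SS_sf <- n * sum((cellm - fit)^2)
  SS_err_s <- 2 * sum((cbind(s_v, s_i) - cbind(sm, sm) -
                         rbind(c(mean(s_v), mean(s_i)))[rep(1, n), ] + gm)^2)
  SS_err_f <- 2 * sum((cbind(f_v, f_i) - cbind(sm, sm) -
                         rbind(c(mean(f_v), mean(f_i)))[rep(1, n), ] + gm)^2)
  SS_tot <- sum((y - gm)^2)
  SS_err_sf <- SS_tot - SS_subj - SS_s - SS_f - SS_sf - SS_err_s - SS_err_f
  SS_err_sf <- max(SS_err_sf, 0)
  err_all <- SS_subj + SS_err_s + SS_err_f + SS_err_sf
  one <- function(effect, SS_e, SS_err) {
    if (SS_e < 1e-12 * max(SS_tot, 1e-300)) {
      F <- 0; p <- 1
    } else {
      F <- (SS_e / 1) / (SS_err / (n - 1))
      p <- stats::pf(F, 1, n - 1, lower.tail = FALSE)
    }
    data.frame(effect = effect, F = F, df1 = 1, df2 = n - 1, p = p,
               eta_g2 = if (SS_e + err_all > 0) SS_e / (SS_e + err_all) else 0,
               stringsAsFactors = FALSE)
  }
  rbind(one("space", SS_s, SS_err_s),
        one("feature", SS_f, SS_err_f),
        one("interaction", SS_sf, SS_err_sf))
}

# subjects x cue-object matrix with completeness checks
.cell_matrix <- function(data, value_col, subject_col, cue_col) {
  need <- c(value_col, subject_col, cue_col)
  if (!all(need %in% names(data)))
    stop_ez("data must have columns ", paste(need, collapse = ", "))
  if (anyNA(data[[value_col]]))
    stop_ez("missing cells; repeated-measures ANOVA requires complete data")
  tab <- table(data[[subject_col]], data[[cue_col]])
  if (!all(tab == 1) || !setequal(colnames(tab), CUE_OBJECTS))
    stop_ez("need exactly one value per subject and cue object ",
            "(SvFv, SvFi, SiFv, SiFi)")
  y <- tapply(data[[value_col]], list(data[[subject_col]], data[[cue_col]]),
              identity)
  y[, CUE_OBJECTS, drop = FALSE]
}

#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Default Bayes factor comparing H1 (standardized effect with a Cauchy
#' prior of scale `r`) against H0 (effect = 0), computed by numerical
#' quadrature of the Zellner-Siow g-prior integral. As `r -> 0` the two
#' hypotheses coincide and the Bayes factor tends to 1.
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of difference scores).
#' @param r Cauchy prior scale (default 0.707, i.e. sqrt(2)/2).
#' @return The Bayes factor BF10 (> 0).
#' @examples
#' jzs_bf(5.23, 31)  # decisive evidence, BF10 > 100
#' @export
jzs_bf <- function(t, n, r = 0.707) {
  stopifnot(is.finite(t), n >= 2, r > 0)
  nu <- n - 1
  # substitute g = r^2 z so the inverse-gamma prior mass is well scaled
  # for any prior width r
  integrand <- function(z) {
    g <- r^2 * z
    (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      z^(-1.5) * exp(-1 / (2 * z)) / sqrt(2 * pi)
  }
  num <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                          subdivisions = 500L)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

#' Paired t-test with effect size and JZS Bayes factor
#'
#' Classical paired t-test plus Cohen's dz (mean difference divided by the
#' standard deviation of the differences, so that `dz = t / sqrt(n)`) and
#' the default JZS Bayes factor.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @param cauchy_scale Cauchy prior scale for the Bayes factor.
#' @return A data frame with `t`, `df`, `p`, `dz`, `bf10`, `mean_diff`.
#' @export
paired_t <- function(x, y, cauchy_scale = 0.707) {
  if (length(x) != length(y)) stop_ez("x and y must have equal length")
  d <- x - y
  n <- length(d)
  if (n < 2) stop_ez("need n >= 2 pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop_ez("zero variance of differences")
  t <- mean(d) / (sd_d / sqrt(n))
  data.frame(t = t, df = n - 1,
             p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
             dz = mean(d) / sd_d,
             bf10 = jzs_bf(t, n, r = cauchy_scale),
             mean_diff = mean(d))
}

#' Within-participant standard errors of condition means
#'
#' Cousineau normalization (subtract each subject's mean across conditions,
#' add back the grand mean) with the Morey bias correction
#' `sqrt(k / (k - 1))` applied to the normalized deviations, where `k` is
#' the number of conditions. Between-subject offsets therefore do not
#' contribute to the error bars.
#'
#' @param data Data frame in long format.
#' @param value_col Response column name.
#' @param subject_col,cond_col Subject and condition column names.
#' @return A data frame with one row per condition: `mean` and `sem`.
#' @export
within_subject_sem <- function(data, value_col, subject_col = "subject_id",
                               cond_col = "cue_object") {
  y <- tapply(data[[value_col]], list(data[[subject_col]], data[[cond_col]]),
              identity)
  if (anyNA(y)) stop_ez("within-subject SEM requires a complete table")
  k <- ncol(y)
  if (k < 2) stop_ez("need at least two conditions")
  norm <- y - rowMeans(y) + mean(y)
  sem <- apply(norm, 2, stats::sd) / sqrt(nrow(y)) * sqrt(k / (k - 1))
  data.frame(condition = colnames(y), mean = colMeans(y), sem = sem,
             row.names = NULL, stringsAsFactors = FALSE)
}
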