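# independent brute-force sums-of-squares oracle via base aov()
anova_oracle <- function(data, value_col) {
  d <- data
  d$subj <- factor(d$subject_id)
  d$space <- factor(ifelse(d$cue_object %in% c("SvFv", "SvFi"), "v", "i"))
  d$feat <- factor(ifelse(d$cue_object %in% c("SvFv", "SiFv"), "v", "i"))
  d$y <- d[[value_col]]
  m <- summary(aov(y ~ space * feat + Error(subj / (space * feat)), data = d))
  get_f <- function(stratum, term) {
    tab <- m[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(space = get_f("Error: subj:space", "space"),
    feature = get_f("Error: subj:feat", "feat"),
    interaction = get_f("Error: subj:space:feat", "space:feat"))
}

make_cell_table <- function(n, effects = c(s = 0, f = 0, sf = 0), sd = 1,
                            seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:n),
                      cue_object = c("SvFv", "SvFi", "SiFv", "SiFi"),
                      stringsAsFactors = FALSE)
  sv <- grid$cue_object %in% c("SvFv", "SvFi")
  fv <- grid$cue_object %in% c("SvFv", "SiFv")
  offs <- rnorm(n)[match(grid$subject_id, sprintf("S%02d", 1:n))]
  grid$value <- offs + effects["s"] * sv + effects["f"] * fv +
    effects["sf"] * sv * fv + rnorm(nrow(grid), 0, sd)
  grid
}

test_that("repeated-measures ANOVA matches an independent brute-force oracle", {
  for (seed in 1:4) {
    tab <- make_cell_table(5, effects = c(s = 0.8, f = 0.3, sf = 0.4),
                           seed = seed)
    ours <- rm_anova_2x2(tab, "value")
    oracle <- anova_oracle(tab, "value")
    expect_equal(ours$F[ours$effect == "space"], unname(oracle["space"]),
                 tolerance = 1e-10)
    expect_equal(ours$F[ours$effect == "feature"], unname(oracle["feature"]),
                 tolerance = 1e-10)
    expect_equal(ours$F[ours$effect == "interaction"],
                 unname(oracle["interaction"]), tolerance = 1e-10)
    expect_equal(ours$df1, rep(1, 3))
    expect_equal(ours$df2, rep(4, 3))
    expect_true(all(ours$eta_g2 >= 0 & ours$eta_g2 <= 1))
  }
})

test_that("F equals the square of the marginal paired t statistic", {
  tab <- make_cell_table(12, effects = c(s = 0.5, f = 0.2, sf = 0.1), seed = 9)
  a <- rm_anova_2x2(tab, "value")
  wide <- tapply(tab$value, list(tab$subject_id, tab$cue_object), identity)
  sv_marg <- rowMeans(wide[, c("SvFv", "SvFi")])
  si_marg <- rowMeans(wide[, c("SiFv", "SiFi")])
  t_space <- paired_t(sv_marg, si_marg)
  expect_equal(a$F[a$effect == "space"], t_space$t^2, tolerance = 1e-10)
  expect_equal(a$p[a$effect == "space"], t_space$p, tolerance = 1e-10)
})

test_that("degenerate tables yield F = 0 and incomplete tables are rejected", {
  tab <- make_cell_table(6, seed = 2)
  # identical cells within every subject: all effect SS are zero
  wide_const <- tab
  wide_const$value <- rnorm(6)[match(wide_const$subject_id,
                                     sprintf("S%02d", 1:6))]
  a <- rm_anova_2x2(wide_const, "value")
  expect_equal(a$F, rep(0, 3))
  expect_equal(a$p, rep(1, 3))
  tab_missing <- tab[-1, ]
  expect_error(rm_anova_2x2(tab_missing, "value"), "one value per subject")
})

test_that("paired t-test reports the closed-form statistic and effect size", {
  set.seed(4)
  # construct differences with mean 1 and sd 1 exactly
  d <- rnorm(31)
  d <- (d - mean(d)) / sd(d) + 1
  res <- paired_t(d, rep(0, 31))
  expect_equal(res$t, sqrt(31), tolerance = 1e-12)
  expect_equal(res$dz, 1, tolerance = 1e-12)
  expect_equal(res$df, 30)
  expect_equal(res$dz, res$t / sqrt(31), tolerance = 1e-12)
  expect_error(paired_t(1:5, 1:5), "zero variance")
  # centred differences: t = 0, evidence favours the null
  d0 <- d - 1
  res0 <- paired_t(d0, rep(0, 31))
  expect_equal(res0$t, 0, tolerance = 1e-12)
  expect_lt(res0$bf10, 1)
})

test_that("JZS Bayes factor matches an independent noncentral-t oracle", {
  # oracle: marginal likelihood over the standardized effect directly
  bf_oracle <- function(t, n, r = 0.707) {
    # dt() with a noncentrality parameter emits precision notices well below
    # the tolerance used here
    f <- function(delta) suppressWarnings(dt(t, n - 1, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r)
    integrate(f, -Inf, Inf, rel.tol = 1e-10)$value / dt(t, n - 1)
  }
  for (t in c(0, 0.8, 2.5, 5.23)) {
    expect_equal(jzs_bf(t, 31), bf_oracle(t, 31), tolerance = 1e-6,
                 label = paste("t =", t))
  }
  expect_equal(jzs_bf(2.1, 20, r = 1), bf_oracle(2.1, 20, r = 1),
               tolerance = 1e-6)
  # decisive-evidence benchmark
  expect_gt(jzs_bf(5.23, 31), 100)
  # monotone in |t| at fixed n
  bfs <- sapply(seq(0, 5, by = 0.5), jzs_bf, n = 25)
  expect_true(all(diff(bfs) > 0))
  # as the prior scale shrinks the hypotheses coincide: BF -> 1
  expect_equal(jzs_bf(2, 25, r = 1e-4), 1, tolerance = 1e-3)
})

test_that("within-participant SEM removes subject offsets", {
  # pure subject offsets, no condition effects: SEM identically zero
  tab <- make_cell_table(5, sd = 0, seed = 3)
  sem <- within_subject_sem(tab, "value", cond_col = "cue_object")
  expect_equal(sem$sem, rep(0, 4), tolerance = 1e-12)
  # k = 2 conditions: hand computation with Morey factor sqrt(2)
  y <- matrix(c(1, 2, 4, 3, 5, 7), ncol = 2)  # 3 subjects x 2 conditions
  d <- data.frame(subject_id = rep(1:3, 2), cue_object = rep(c("A", "B"), each = 3),
                  value = c(y))
  norm <- y - rowMeans(y) + mean(y)
  hand <- apply(norm, 2, sd) / sqrt(3) * sqrt(2)
  sem2 <- within_subject_sem(d, "value", cond_col = "cue_object")
  expect_equal(sem2$sem, unname(hand))
  # invariant to adding per-subject constants
  d_shift <- d
  d_shift$value <- d_shift$value + rep(c(10, -5, 3), 2)
  sem3 <- within_subject_sem(d_shift, "value", cond_col = "cue_object")
  expect_equal(sem3$sem, sem2$sem)
  expect_error(within_subject_sem(d[d$cue_object == "A", ], "value",
                                  cond_col = "cue_object"), "two conditions")
})

test_that("the ANOVA holds its nominal type-I error under the null", {
  set.seed(123)
  n_sim <- 500
  p_int <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    grid <- expand.grid(subject_id = 1:12,
                        cue_object = c("SvFv", "SvFi", "SiFv", "SiFi"))
    grid$value <- rnorm(48)
    p_int[i] <- rm_anova_2x2(grid, "value")$p[3]
  }
  rate <- mean(p_int < 0.05)
  # binomial 3-sigma band around 0.05 at 500 simulations
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})
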