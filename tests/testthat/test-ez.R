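test_that("forward equations honour construction identities and limits", {
  # v*a/s^2 = ln 3 puts accuracy at exactly 0.75
  s <- 0.1
  a <- 0.1
  v <- log(3) * s^2 / a
  expect_equal(ez_forward(v, a, 0.2, s)$Pc, 0.75)
  # v -> 0 analytic limits
  f0 <- ez_forward(0, a = 0.1, ter = 0.3, s = 0.1)
  expect_equal(f0$Pc, 0.5)
  expect_equal(f0$MRT, 0.25 + 0.3)          # MDT -> a^2 / (4 s^2)
  expect_equal(f0$VRT, 0.1^4 / (24 * 0.1^4))  # VRT -> a^4 / (24 s^4)
  # the limit branch is continuous with the exact expressions
  f_eps <- ez_forward(1e-6, 0.1, 0.3)
  expect_equal(f_eps$MRT, f0$MRT, tolerance = 1e-4)
  expect_equal(f_eps$VRT, f0$VRT, tolerance = 1e-4)
  expect_error(ez_forward(0.1, a = -0.1, ter = 0.2), "a > 0")
})

test_that("inversion is the exact inverse of the forward model", {
  f <- ez_forward(0.1, 0.14, 0.3)
  est <- ez_inverse(f$Pc, f$MRT, f$VRT)
  expect_equal(est$v, 0.1, tolerance = 1e-10)
  expect_equal(est$a, 0.14, tolerance = 1e-10)
  expect_equal(est$ter, 0.3, tolerance = 1e-10)

  # property sweep over the plausible parameter ranges
  set.seed(99)
  for (i in 1:100) {
    v <- runif(1, 0.02, 0.3); a <- runif(1, 0.05, 0.15); ter <- runif(1, 0.1, 0.4)
    f <- ez_forward(v, a, ter)
    est <- ez_inverse(f$Pc, f$MRT, f$VRT)
    expect_lt(max(abs(c(est$v - v, est$a - a, est$ter - ter) / c(v, a, ter))),
              1e-8)
  }
  # below-chance accuracy maps to negative drift, sign-consistent with Pc - 1/2
  est_neg <- ez_inverse(0.3, 0.5, 0.05)
  expect_lt(est_neg$v, 0)
  expect_gt(est_neg$a, 0)
})

test_that("degenerate accuracies get the 1/(2n) edge correction", {
  f <- ez_forward(0.2, 0.1, 0.25)
  expect_warning(est <- ez_inverse(1, f$MRT, f$VRT, n = 100), "edge correction")
  # proceeds with Pc = 1 - 1/(2n) = 0.995
  ref <- ez_inverse(0.995, f$MRT, f$VRT)
  expect_equal(est$v, ref$v)
  expect_true(est$corrected)
  expect_warning(est05 <- ez_inverse(0.5, f$MRT, f$VRT, n = 100),
                 "edge correction")
  expect_equal(est05$v, ez_inverse(0.5 + 1 / 200, f$MRT, f$VRT)$v)
  expect_error(ez_inverse(1, f$MRT, f$VRT), "n")
  expect_error(ez_inverse(1, f$MRT, f$VRT, n = 100, edge_correction = "none"),
               "edge correction")
  expect_error(ez_inverse(0.8, 0.5, 0), "VRT")
})

test_that("boundary separation scales as s^2 at fixed accuracy and drift scales with s", {
  f <- ez_forward(0.1, 0.1, 0.3, s = 0.1)
  e1 <- ez_inverse(f$Pc, f$MRT, f$VRT, s = 0.1)
  e2 <- ez_inverse(f$Pc, f$MRT, f$VRT, s = 1)
  expect_equal(e2$L, e1$L)
  expect_equal(e2$v / e1$v, 10)      # v proportional to s
  expect_equal(e2$a / e1$a, 10)      # a = s^2 L / v grows by s^2/s
})

test_that("cell-level fitting flags low-n cells and keeps the rest", {
  cells <- data.frame(subject_id = "S01",
                      cue_object = c("SvFv", "SvFi", "SiFv", "SiFi"),
                      n_total = c(100, 100, 100, 5),
                      n_correct = c(80, 70, 60, 3),
                      Pc = c(0.8, 0.7, 0.6, 0.6),
                      MRT = c(0.5, 0.52, 0.55, 0.5),
                      VRT = c(0.05, 0.06, 0.07, 0.05))
  est <- ez_fit_cells(cells, min_n = 10)
  expect_true(est$low_n[4])
  expect_true(is.na(est$v[4]))
  expect_true(all(!is.na(est$v[1:3])))
  # estimates round-trip to the observed moments
  f <- ez_forward(est$v[1], est$a[1], est$ter[1])
  expect_equal(f$Pc, 0.8, tolerance = 1e-10)
  expect_equal(f$MRT, 0.5, tolerance = 1e-10)
  expect_equal(f$VRT, 0.05, tolerance = 1e-10)
})
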