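test_that("exclusion stages remove the right trials in the right order", {
  log <- rbind(
    make_log(10, block_index = 0L),                       # practice
    make_log(10),                                         # clean
    make_log(5, gaze_contaminated = TRUE),                # gaze
    make_log(3, response = "none", rt_s = NA),            # no keypress
    make_log(2, rt_s = 0.1))                              # fast
  out <- apply_exclusions(log, fast_cutoff_s = 0.25)
  rep <- out$report
  expect_equal(rep$stage, c("practice_block", "gaze_contaminated",
                            "non_response", "fast_rt_below_0.25s"))
  expect_equal(rep$n_removed, c(10, 5, 3, 2))
  # report reconciles exactly: n_in - n_removed = n_remaining, chained
  expect_equal(rep$n_in - rep$n_removed, rep$n_remaining)
  expect_equal(rep$n_in[-1], rep$n_remaining[-nrow(rep)])
  expect_equal(nrow(out$trials), 10)
  # idempotent: re-running on the filtered log removes nothing
  again <- apply_exclusions(out$trials, fast_cutoff_s = 0.25,
                            practice_blocks = 1L)
  expect_equal(sum(again$report$n_removed), 0)
})

test_that("gaze removal percentage matches the flag rate and fast cutoff is exact", {
  set.seed(1)
  log <- make_log(1000)
  log$gaze_contaminated <- seq_len(1000) <= 100   # exactly 10%
  out <- apply_exclusions(log)
  expect_equal(out$report$pct_removed[out$report$stage == "gaze_contaminated"],
               10)
  log2 <- make_log(100, rt_s = seq(0.01, 1, length.out = 100))
  out2 <- apply_exclusions(log2, fast_cutoff_s = 0.25)
  expect_true(all(out2$trials$rt_s >= 0.25))
  expect_equal(out2$report$n_removed[out2$report$stage == "fast_rt_below_0.25s"],
               sum(log2$rt_s < 0.25))
})

test_that("unknown response codes are rejected", {
  log <- make_log(4)
  log$response[2] <- "space"
  expect_error(apply_exclusions(log), "unknown response codes")
})

test_that("condition cells carry exact accuracy and correct-RT moments", {
  log <- rbind(make_log(4, cue_object = "SvFv", response = "right",
                        rt_s = c(0.4, 0.6, 0.4, 0.6)),
               make_log(4, cue_object = "SvFi", response = "right", rt_s = 0.5),
               make_log(4, cue_object = "SiFv", response = "right", rt_s = 0.5),
               make_log(4, cue_object = "SiFi",
                        response = c("right", "right", "left", "left"),
                        rt_s = 0.5))
  cells <- summarize_cells(log)
  svfv <- cells[cells$cue_object == "SvFv", ]
  expect_equal(svfv$Pc, 1)
  expect_equal(svfv$MRT, 0.5)
  expect_equal(svfv$VRT, var(c(0.4, 0.6, 0.4, 0.6)))  # n-1 denominator
  # hand value for two correct RTs {0.4, 0.6}
  log2 <- make_log(2, rt_s = c(0.4, 0.6))
  suppressMessages(c2 <- summarize_cells(log2, drop_subjects = FALSE))
  expect_equal(c2$MRT[c2$cue_object == "SvFv"], 0.5)
  expect_equal(c2$VRT[c2$cue_object == "SvFv"], 0.02)
  # all-correct constant-RT cell
  sifi <- cells[cells$cue_object == "SiFi", ]
  expect_equal(sifi$Pc, 0.5)
  expect_equal(sifi$n_correct, 2)
})

test_that("subjects with nearly empty cells are flagged and dropped", {
  good <- do.call(rbind, lapply(c("SvFv", "SvFi", "SiFv", "SiFi"),
    function(co) make_log(6, cue_object = co)))
  bad <- good
  bad$subject_id <- "S02"
  bad$response[bad$cue_object == "SiFi"] <- c("left", "left", "left",
                                              "left", "left", "right")
  # S02 has one correct SiFi trial only
  expect_message(cells <- summarize_cells(rbind(good, bad)), "S02")
  expect_false("S02" %in% cells$subject_id)
  expect_equal(attr(cells, "dropped_subjects"), "S02")
  suppressMessages(kept <- summarize_cells(rbind(good, bad),
                                           drop_subjects = FALSE))
  expect_true("S02" %in% kept$subject_id)
})

test_that("pooled cell accuracy reproduces overall post-exclusion accuracy", {
  log <- simulate_session(design_spec("E1"), observer_params(), seed = 31)
  out <- apply_exclusions(log)
  cells <- summarize_cells(out$trials)
  pooled <- sum(cells$n_correct) / sum(cells$n_total)
  overall <- mean(out$trials$response == out$trials$gap_side)
  expect_equal(pooled, overall)
})
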