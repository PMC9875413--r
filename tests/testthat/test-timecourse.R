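# Exhaustion-state sampling and the built-in timecourses.

test_that("exhaustion states respect the type invariants and determinism", {
  tc <- llc_rt_timecourse()
  for (day in tc$timepoints) {
    st <- sample_exhaustion_state(tc, day, seed = 11L)
    expect_gte(st$terminal_tex_frac, 0)
    expect_lte(st$terminal_tex_frac, 1)
    expect_lte(st$early_tex_frac + st$terminal_tex_frac, 1)
    expect_equal(st$e_t_ratio, st$early_tex_frac / st$terminal_tex_frac)
    expect_gt(st$pd1_mfi, 0)
  }
  expect_identical(sample_exhaustion_state(tc, 7, 3L),
                   sample_exhaustion_state(tc, 7, 3L))
  expect_false(identical(sample_exhaustion_state(tc, 7, 3L),
                         sample_exhaustion_state(tc, 7, 4L)))
})

test_that("a zero-sd timepoint returns its mean exactly", {
  tc <- cohort_timecourse("LLC", 0L, 0.37, 0)
  st <- sample_exhaustion_state(tc, 0L, seed = 1L)
  expect_identical(st$terminal_tex_frac, 0.37)
})

test_that("an unknown day raises an error naming the missing timepoint", {
  expect_error(sample_exhaustion_state(llc_rt_timecourse(), 5, 1L), "day 5")
})

test_that("LLC post-irradiation timecourse is calibrated to its anchors", {
  tc <- llc_rt_timecourse()
  expect_equal(tc$terminal_tex_mean[tc$timepoints == 0], 0.40, tolerance = 0.05)
  peak <- max(tc$terminal_tex_mean)
  expect_gte(peak, 0.6944)
  expect_lte(peak, 0.7635)
  expect_true(which.max(tc$terminal_tex_mean) %in%
                which(tc$timepoints %in% c(7, 14)))
  expect_lt(tc$terminal_tex_mean[tc$timepoints == 21],
            tc$terminal_tex_mean[tc$timepoints == 0])
  # model baselines: LLC heavily exhausted, B16 less so
  expect_equal(llc_ici_timecourse()$terminal_tex_mean[1], 0.40, tolerance = 0.05)
  expect_equal(b16_ici_timecourse()$terminal_tex_mean[1], 0.20, tolerance = 0.05)
})

test_that("day-7 cohorts are more exhausted than day-0 cohorts", {
  tc <- llc_rt_timecourse()
  d0 <- vapply(1:40, function(i)
    sample_exhaustion_state(tc, 0, seed = i)$terminal_tex_frac, numeric(1))
  d7 <- vapply(1:40, function(i)
    sample_exhaustion_state(tc, 7, seed = 1000L + i)$terminal_tex_frac, numeric(1))
  expect_gt(mean(d7), mean(d0))
})
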