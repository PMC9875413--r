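# Lin's concordance correlation coefficient and the robustness filter.

test_that("closed-form CCC values are exact", {
  expect_equal(lin_ccc(c(1, 5, 9, 2), c(1, 5, 9, 2)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 4, 6)), 8 / 22)
  expect_lt(lin_ccc(c(1, 2, 3), c(3, 2, 1)), 0)
})

test_that("degenerate series follow the stated conventions", {
  expect_equal(lin_ccc(c(2, 2, 2), c(2, 2, 2)), 1)        # identical constants
  d <- lin_ccc(c(2, 2, 2), c(3, 3, 3))
  expect_equal(as.numeric(d), 2 * 0 / (0 + 0 + 1))        # zero, flagged
  expect_error(lin_ccc(1:3, 1:4), "length")
  expect_error(lin_ccc(1:2, 1:2), "at least 3")
  expect_error(lin_ccc(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("CCC never exceeds Pearson correlation in magnitude", {
  set.seed(600)
  for (i in 1:50) {
    x <- rnorm(10); y <- 0.5 * x + rnorm(10, sd = runif(1, 0.1, 2)) + runif(1, -2, 2)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("CCC is invariant to a shared affine map and penalized by a shift", {
  set.seed(601)
  x <- rnorm(12); y <- x + rnorm(12, sd = 0.3)
  base <- lin_ccc(x, y)
  expect_equal(lin_ccc(2 * x + 1, 2 * y + 1), base)
  expect_lt(lin_ccc(x, y + 1.5), base)
})

test_that("the robustness filter retains by strict threshold in catalog order", {
  tab <- data.frame(subject_id = sprintf("S%d", 1:6),
                    a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6),
                    c = c(6, 1, 5, 2, 4, 3))
  noisy <- tab
  noisy$b <- tab$b + c(0.1, -0.2, 0.1, 0, -0.1, 0.2)
  noisy$c <- rev(tab$c)
  rep_all <- filter_features(tab, tab, "pet")
  expect_true(all(rep_all$pass))
  rep1 <- filter_features(tab, noisy, "pet")
  expect_identical(rep1$feature, c("a", "b", "c"))  # catalog order preserved
  expect_true(rep1$pass[1] && rep1$pass[2])
  impossible <- filter_features(tab, tab, "pet", threshold = 1.01)
  expect_identical(attr(impossible, "n_retained"), 0L)
  bad <- tab; bad$subject_id <- rev(tab$subject_id)
  expect_error(filter_features(tab, bad, "pet"), "subjects")
})

test_that("small perturbations keep summary features concordant across a cohort", {
  # ROI-mean-type features survive a gentle test-retest protocol
  tmpl <- phantom_spec()
  small <- list(shift_mm = c(0.15, -0.1, 0.1), intensity_scale_sd = 0,
                noise_seed_offset = 1L)
  rt <- exhaustscope:::generate_retest_cohort(12, llc_rt_timecourse(),
                                              c(0L, 7L, 14L), tmpl,
                                              seed = 31L, perturbation = small)
  test_tab <- extract_cohort_features(rt$test, "pet")
  retest_tab <- extract_cohort_features(rt$retest, "pet")
  rep <- filter_features(test_tab, retest_tab, "pet")
  expect_gt(rep$ccc[rep$feature == "ID_Mean"], 0.9)
  expect_gt(rep$ccc[rep$feature == "GLCM_Homogeneity2"], 0.9)
  # frozen golden retained count for this seed and protocol
  expect_identical(attr(rep, "n_retained"), .golden_small_pert_retained)
})

test_that("noise dwarfing the lesion contrast destroys texture concordance", {
  tmpl <- phantom_spec(noise_sigma = 2)  # noise >> suppression depth
  rt <- exhaustscope:::generate_retest_cohort(8, llc_rt_timecourse(),
                                              c(0L, 7L, 14L), tmpl, seed = 32L,
                                              perturbation = list(
                                                shift_mm = c(0.15, -0.1, 0.1),
                                                intensity_scale_sd = 0.02,
                                                noise_seed_offset = 1L))
  rep <- filter_features(extract_cohort_features(rt$test, "pet"),
                         extract_cohort_features(rt$retest, "pet"), "pet")
  tex <- grepl("^GLCM_(Homogeneity2|InverseVariance|Contrast)$", rep$feature)
  expect_true(all(rep$ccc[tex] < 0.65))
})
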