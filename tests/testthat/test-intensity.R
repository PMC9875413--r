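# First-order features, both flavors.

test_that("population moments match hand computation on {1,1,3,3}", {
  scan <- tiny_scan(c(1, 1, 3, 3), c(4, 1, 1))
  f <- intensity_direct_features(scan, full_mask(c(4, 1, 1)))
  expect_equal(unname(f["Variance"]), 1)   # population variance
  expect_equal(unname(f["Kurtosis"]), 1)   # m4/m2^2 = 1/1
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Energy"]), 20)
})

test_that("kurtosis is the non-excess Pearson moment ratio (normal gives ~3)", {
  set.seed(500)
  n <- 1e5
  scan <- tiny_scan(rnorm(n) + 10, c(n, 1, 1))
  f <- intensity_direct_features(scan, full_mask(c(n, 1, 1)))
  expect_equal(unname(f["Kurtosis"]), 3, tolerance = 0.1)
})

test_that("a constant ROI triggers the degenerate policy", {
  scan <- tiny_scan(rep(4, 27), c(3, 3, 3))
  f <- intensity_direct_features(scan, full_mask(c(3, 3, 3)))
  expect_equal(unname(f["Kurtosis"]), 0)
  expect_equal(unname(f["Skewness"]), 0)
  expect_true(attr(f, "degenerate"))
  lv <- discretize(scan, full_mask(c(3, 3, 3)))
  fh <- intensity_histogram_features(lv)
  expect_equal(unname(fh["Kurtosis"]), 0)
  expect_true(attr(fh, "degenerate"))
})

test_that("histogram features are rescale-invariant, direct features are not", {
  ph <- default_phantom()
  suv <- to_suv(ph$pet)
  resc <- suv; resc$voxels <- 1.8 * suv$voxels + 0.25
  lv1 <- discretize(suv, ph$mask); lv2 <- discretize(resc, ph$mask)
  expect_identical(intensity_histogram_features(lv1),
                   intensity_histogram_features(lv2))
  expect_identical(glcm_features(glcm(lv1)), glcm_features(glcm(lv2)))
  expect_identical(glrlm_features(glrlm(lv1)), glrlm_features(glrlm(lv2)))
  d1 <- intensity_direct_features(suv, ph$mask)
  d2 <- intensity_direct_features(resc, ph$mask)
  expect_false(isTRUE(all.equal(d1[["Mean"]], d2[["Mean"]])))
  expect_equal(d2[["Mean"]], 1.8 * d1[["Mean"]] + 0.25)
})
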