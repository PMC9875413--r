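# Gray-level co-occurrence matrix and its statistics.

test_that("the hand-enumerated 2x2 single-direction matrix is exact", {
  # levels [[1,1],[1,2]] in-plane, offset along the second axis
  lv <- levels_array(c(1, 1, 1, 2), c(2, 2, 1), 2L)
  cfg <- texture_config(directions = matrix(c(0L, 1L, 0L), 1))
  P <- glcm(lv, cfg)
  expect_equal(P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  f <- glcm_features(P)
  expect_equal(unname(f["Contrast"]), 0.5)
  expect_equal(unname(f["Homogeneity2"]), 0.75)
  expect_equal(unname(f["InverseVariance"]), 0.5)
})

test_that("a homogeneous ROI has purely diagonal co-occurrence mass", {
  lv <- levels_array(rep(1L, 27), c(3, 3, 3), 4L)
  P <- glcm(lv)
  expect_equal(sum(P * (row(P) != col(P))), 0)
  f <- glcm_features(P)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Homogeneity2"]), 1)
  expect_equal(unname(f["InverseVariance"]), 0)
})

test_that("matrices match the brute-force pair enumerator on random small ROIs", {
  set.seed(401)
  cfg <- texture_config()
  for (i in 1:30) {
    lv <- random_small_roi()
    P_fast <- tryCatch(glcm(lv, cfg), error = function(e) NULL)
    if (is.null(P_fast)) next  # degenerate ROI, oracle would also be empty
    expect_equal(P_fast, brute_glcm(lv, cfg$directions), tolerance = 1e-12)
  }
})

test_that("normalization and definition bounds hold for arbitrary matrices", {
  set.seed(402)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    P <- matrix(rexp(n * n), n, n)
    P <- (P + t(P)) / (2 * sum(P))
    f <- glcm_features(P)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_gt(f[["Homogeneity2"]], 0)
    expect_lte(f[["Homogeneity2"]], 1)
    expect_gte(f[["Contrast"]], 0)
    expect_gte(f[["InverseVariance"]], 0)
  }
  expect_error(glcm_features(matrix(1, 2, 2)), "not normalized")
})

test_that("degenerate textures and redundant directions are rejected", {
  single <- levels_array(1L, c(1, 1, 1), 2L)
  expect_error(glcm(single), "degenerate")
  expect_error(texture_config(directions = rbind(c(1, 0, 0), c(-1, 0, 0))),
               "negation")
  expect_identical(nrow(directions_3d()), 13L)
})
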