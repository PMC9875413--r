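# Phantom generation: geometry, heterogeneity coupling, determinism,
# test-retest pairs and cohorts.

test_that("zero heterogeneity and zero noise give a perfectly flat lesion", {
  spec <- phantom_spec(heterogeneity_gain = 0, noise_sigma = 0, seed = 3L)
  ph <- generate_phantom(spec, default_state(0.7))
  roi <- ph$pet$voxels[ph$mask$voxels]
  expect_equal(diff(range(roi)), 0)
  suv <- to_suv(ph$pet)
  expect_equal(unique(suv$voxels[ph$mask$voxels]), spec$base_suv)
})

test_that("higher terminal-Tex fraction strictly increases ROI activity variance", {
  spec <- phantom_spec(seed = 8L)
  lo <- generate_phantom(spec, default_state(0.2))
  hi <- generate_phantom(spec, default_state(0.75))
  expect_gt(var(hi$pet$voxels[hi$mask$voxels]),
            var(lo$pet$voxels[lo$mask$voxels]))
})

test_that("rasterized mask volume matches the analytic ellipsoid volume", {
  spec <- phantom_spec(seed = 2L)
  ph <- generate_phantom(spec, default_state())
  v_mask <- sum(ph$mask$voxels) * prod(spec$voxel_spacing_mm)
  v_true <- 4 / 3 * pi * prod(spec$tumor_semi_axes_mm)
  # one voxel-shell tolerance: surface area x voxel edge
  shell <- 4 * pi * mean(spec$tumor_semi_axes_mm)^2 * max(spec$voxel_spacing_mm)
  expect_lt(abs(v_mask - v_true), shell)
})

test_that("phantoms are a pure function of spec and state", {
  spec <- phantom_spec(seed = 21L)
  a <- generate_phantom(spec, default_state())
  b <- generate_phantom(spec, default_state())
  expect_identical(a$pet$voxels, b$pet$voxels)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
})

test_that("a tumor larger than the grid raises a geometry error", {
  expect_error(
    generate_phantom(phantom_spec(grid_shape = c(12, 12, 12), seed = 1L),
                     default_state()),
    "does not fit")
})

test_that("zero perturbation reproduces the test scan voxelwise", {
  pair <- generate_test_retest_pair(
    phantom_spec(seed = 12L), default_state(),
    perturbation = list(shift_mm = c(0, 0, 0), intensity_scale_sd = 0,
                        noise_seed_offset = 0L))
  expect_identical(pair$test$pet$voxels, pair$retest$pet$voxels)
  expect_identical(pair$test$mask$voxels, pair$retest$mask$voxels)
})

test_that("the default perturbation moves the mask and changes intensities", {
  pair <- generate_test_retest_pair(phantom_spec(seed = 12L), default_state())
  expect_false(identical(pair$test$mask$voxels, pair$retest$mask$voxels))
  expect_false(identical(pair$test$pet$voxels, pair$retest$pet$voxels))
  # same latent lesion: ROI voxel counts stay close under sub-grid shift
  expect_lt(abs(sum(pair$test$mask$voxels) - sum(pair$retest$mask$voxels)) /
              sum(pair$test$mask$voxels), 0.05)
})

test_that("cohort median split labels exactly half the subjects high", {
  co <- generate_cohort(20, llc_rt_timecourse(), c(0L, 7L, 14L),
                        phantom_spec(), seed = 6L)
  expect_identical(sum(co$ground_truth$label_high), 10L)
  expect_error(generate_cohort(3, llc_rt_timecourse(), 0L, phantom_spec(), 1L),
               ">= 4")
  co2 <- generate_cohort(20, llc_rt_timecourse(), c(0L, 7L, 14L),
                         phantom_spec(), seed = 6L)
  expect_identical(co$ground_truth, co2$ground_truth)
})

test_that("terminal-Tex couples monotonically to ROI activity variance across a cohort", {
  co <- generate_cohort(30, llc_rt_timecourse(), c(0L, 3L, 7L, 14L, 21L),
                        phantom_spec(), seed = 17L)
  v <- vapply(co$subjects, function(s) var(s$pet$voxels[s$mask$voxels]), numeric(1))
  rho <- cor(co$ground_truth$terminal_tex_frac, v, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("combining cohorts recomputes the label from the pooled median", {
  a <- generate_cohort(6, llc_ici_timecourse(), 0L, phantom_spec(), seed = 1L)
  b <- generate_cohort(6, llc_rt_timecourse(), 7L, phantom_spec(), seed = 2L)
  ab <- combine_cohorts(a, b)
  tex <- ab$ground_truth$terminal_tex_frac
  expect_identical(ab$ground_truth$label_high, tex > median(tex))
  # day-7 post-RT subjects are the exhausted half
  expect_gt(mean(ab$ground_truth$label_high[ab$ground_truth$day == 7]),
            mean(ab$ground_truth$label_high[ab$ground_truth$day == 0]))
})
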