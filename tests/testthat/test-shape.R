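# Shape features: mesh surface area, compactness, convex hull, diameter.

test_that("cube compactness approaches the closed form pi/6 as the cube grows", {
  f16 <- shape_features(cube_mask(16))
  f40 <- shape_features(cube_mask(40))
  expect_equal(unname(f16["Volume"]), 16^3)
  expect_equal(unname(f40["Volume"]), 40^3)
  err16 <- abs(f16[["Compactness2"]] - pi / 6)
  err40 <- abs(f40[["Compactness2"]] - pi / 6)
  expect_lt(err40, err16)          # mesh converges with resolution
  expect_lt(err40, 0.05)
  # hull of cube voxel centers is the inner (s-1)^3 cube, exactly
  expect_equal(unname(f40["ConvexHullVolume3D"]), 39^3)
  expect_equal(unname(f40["Maximum3DDiameter"]), sqrt(3) * 39)
})

test_that("a digital ball is nearly spherical by Compactness2", {
  for (r in c(8L, 12L)) {
    f <- shape_features(ball_mask(r))
    expect_lt(abs(f[["Compactness2"]] - 1), 0.15)
    expect_lt(abs(f[["Sphericity"]] - 1), 0.06)
  }
})

test_that("convex hull volume is exact on closed-form polytopes", {
  # cross-polytope |x|+|y|+|z| <= r over integer points: hull volume 4r^3/3
  r <- 6
  co <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  oct <- co[rowSums(abs(co)) <= r, ]
  expect_equal(exhaustscope:::convex_hull_volume(oct), 4 * r^3 / 3)
  # interior points do not change the hull
  shell <- oct[rowSums(abs(oct)) == r, ]
  corners <- rbind(c(r,0,0), c(-r,0,0), c(0,r,0), c(0,-r,0), c(0,0,r), c(0,0,-r))
  expect_equal(exhaustscope:::convex_hull_volume(shell),
               exhaustscope:::convex_hull_volume(corners))
  # degenerate (coplanar) cloud has zero hull volume
  flat <- cbind(runif(30), runif(30), 1)
  expect_equal(exhaustscope:::convex_hull_volume(flat), 0)
})

test_that("the hull of a convex mask matches its volume within a half-voxel shell", {
  ph <- default_phantom()
  f <- shape_features(ph$mask)
  v <- f[["Volume"]]; hull <- f[["ConvexHullVolume3D"]]; area <- f[["SurfaceArea"]]
  shell <- area * max(ph$mask$spacing_mm) / 2
  expect_lte(hull, v + shell)
  expect_gte(hull, v - shell)
})

test_that("too-small masks are rejected", {
  expect_error(shape_features(roi_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                                       c(1, 1, 1), minimal = FALSE)),
               "too small")
})
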