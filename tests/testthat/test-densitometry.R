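test_that("calibration fits the exact line through two points", {
  m <- fitCalibration(c(0, 1000), c(1, 2))
  expect_equal(m@slope, 0.001)
  expect_equal(m@intercept, 1.0)
  expect_equal(m@rSquared, 1.0)
})

test_that("collinear samples give r-squared of one and noisy fits match the normal equations", {
  hu <- c(-50, 0, 200, 800, 1200)
  m <- fitCalibration(hu, 1 + 0.0012 * hu)
  expect_equal(m@rSquared, 1.0, tolerance = 1e-12)

  set.seed(11)
  hu8 <- c(-80, 0, 100, 250, 400, 700, 950, 1300)
  dens <- 0.95 + 0.0011 * hu8 + rnorm(8, 0, 0.02)
  fit <- fitCalibration(hu8, dens)
  ref <- oracleOLS(hu8, dens)
  expect_equal(fit@intercept, ref[1], tolerance = 1e-10)
  expect_equal(fit@slope, ref[2], tolerance = 1e-10)
})

test_that("degenerate calibration input is rejected", {
  expect_error(fitCalibration(c(100), c(1.2)), "calibration error")
  expect_error(fitCalibration(c(100, 100, 100), c(1, 1.1, 1.2)),
               "calibration error")
})

test_that("BMD to CHA conversion hits its fixed points", {
  v <- DensityVolume(array(c(1.0, 3.18, 2.09, 0.9), c(4, 1, 1)), 150, "BMD")
  cha <- bmdToCha(v)
  expect_identical(densityUnits(cha), "CHA")
  vals <- voxelValues(cha)
  expect_equal(vals[1], 0, tolerance = 1e-14)           # pure water
  expect_equal(vals[2], 3.18, tolerance = 1e-12)        # fixed point at D_CHA
  expect_equal(vals[3], (2.09 - 1) / 2.18 * 3.18, tolerance = 1e-14)
  expect_lt(vals[4], 0)                                 # sub-water preserved
})

test_that("CHA to ash conversion is the documented affine map", {
  v <- DensityVolume(array(c(0, 1, 3.18), c(3, 1, 1)), 150, "CHA")
  ash <- chaToAsh(v)
  expect_identical(densityUnits(ash), "ash")
  vals <- voxelValues(ash)
  expect_equal(vals[1], 0.0633, tolerance = 1e-14)
  expect_equal(vals[2], 0.9503, tolerance = 1e-14)
  expect_equal(vals[3], 0.0633 + 0.887 * 3.18, tolerance = 1e-14)
})

test_that("conversions enforce the units tag", {
  hu <- DensityVolume(array(0, c(2, 2, 2)), 150, "HU")
  expect_error(bmdToCha(hu), "unit error")
  expect_error(chaToAsh(hu), "unit error")
  expect_error(applyCalibration(fitCalibration(c(0, 1000), c(1, 2)),
                                bmdToCha(DensityVolume(array(1.5, c(2, 2, 2)),
                                                       150, "BMD"))),
               "unit error")
})

test_that("density maps are monotone and invert to 1e-10", {
  set.seed(3)
  vals <- array(runif(64, 0.8, 3.2), c(4, 4, 4))
  v <- DensityVolume(vals, 150, "BMD")
  cha <- bmdToCha(v)
  ash <- chaToAsh(cha)
  # strict monotone: voxel ordering preserved through both maps
  expect_identical(order(vals), order(voxelValues(cha)))
  expect_identical(order(vals), order(voxelValues(ash)))
  # analytic round trip
  back <- chaToBmd(ashToCha(ash))
  expect_equal(voxelValues(back), vals, tolerance = 1e-10)
})

test_that("applyCalibration maps HU volumes to BMD", {
  m <- fitCalibration(c(0, 1000), c(1, 2))
  hu <- DensityVolume(array(c(0, 500, 1000), c(3, 1, 1)), 150, "HU")
  bmd <- applyCalibration(m, hu)
  expect_identical(densityUnits(bmd), "BMD")
  expect_equal(as.vector(voxelValues(bmd)), c(1, 1.5, 2))
})
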