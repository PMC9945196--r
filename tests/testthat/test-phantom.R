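test_that("plate phantom hits the geometric BV/TV and is deterministic", {
  spec <- phantomSpec(gridSize = 32L, rodFraction = 0, seed = 7L)
  ph <- generatePhantom(spec)
  target <- spec@plateThickness / spec@plateSpacing
  # voxel quantization: each plate's thickness is resolved to +/- 1 voxel
  expect_lt(abs(mean(ph$mask) - target), spec@spacing / spec@plateSpacing)

  ph2 <- generatePhantom(spec)
  expect_identical(voxelValues(ph$volume), voxelValues(ph2$volume))
  expect_identical(ph$mask, ph2$mask)
})

test_that("rod fraction zero yields plates only; bone voxels carry bone BMD", {
  spec <- phantomSpec(gridSize = 16L, rodFraction = 0, seed = 3L,
                      orientation = "y")
  ph <- generatePhantom(spec)
  # every mask cross-section along the plate normal is all-or-nothing
  perSlice <- apply(ph$mask, 2, mean)
  expect_true(all(perSlice %in% c(0, 1)))

  boneBmd <- spec@boneCha / 3.18 * 2.18 + 1
  expect_equal(unique(voxelValues(ph$volume)[ph$mask]), boneBmd)
  expect_equal(unique(voxelValues(ph$volume)[!ph$mask]), spec@marrowBmd)

  expect_error(phantomSpec(plateThickness = 700, plateSpacing = 650),
               "plateThickness")
})

test_that("scanner identity model passes a volume through unchanged", {
  ph <- generatePhantom(phantomSpec(gridSize = 12L, seed = 5L))
  out <- simulateScanner(ph$volume,
                         scannerModel(psfFwhm = 0, noiseStd = 0,
                                      outputSpacing = 150))
  expect_identical(voxelValues(out), voxelValues(ph$volume))
})

test_that("PSF blurring conserves density mass on a padded phantom", {
  inner <- generatePhantom(phantomSpec(gridSize = 16L, seed = 9L))
  d <- c(32, 32, 32)
  vals <- array(1.0, d)  # marrow padding
  vals[9:24, 9:24, 9:24] <- voxelValues(inner$volume)
  v <- DensityVolume(vals, 150, "BMD")
  out <- simulateScanner(v, scannerModel(psfFwhm = 400, noiseStd = 0,
                                         outputSpacing = 150))
  expect_lt(abs(sum(voxelValues(out)) - sum(vals)) / sum(vals), 0.001)
})

test_that("a wider PSF inflates the apparent structure thickness", {
  # fine 100 um grid so the half-occupancy boundary moves by whole voxels
  ph <- generatePhantom(phantomSpec(gridSize = 36L, spacing = 100,
                                    plateThickness = 300, plateSpacing = 700,
                                    rodFraction = 0, seed = 11L,
                                    orientation = "x"))
  # a lenient occupancy threshold captures partial-volume voxels (the 0.5
  # contour of a blurred step sits exactly on the edge and would not move)
  th <- vapply(c(100, 250, 400), function(fw) {
    img <- simulateScanner(ph$volume,
                           scannerModel(psfFwhm = fw, noiseStd = 0,
                                        outputSpacing = 100))
    tbThicknessProxy(bvfFromBmd(img) > 0.25, 100, axis = "x")
  }, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("cohorts are reproducible and LR/HR share ground truth", {
  c1 <- generateCohort(3, seed = 15L,
                       baseSpec = phantomSpec(gridSize = 12L, seed = 1L))
  c2 <- generateCohort(3, seed = 15L,
                       baseSpec = phantomSpec(gridSize = 12L, seed = 1L))
  for (i in 1:3) {
    expect_identical(voxelValues(c1[[i]]$lr), voxelValues(c2[[i]]$lr))
    expect_identical(c1[[i]]$mask, c2[[i]]$mask)
  }
  bvtv <- vapply(c1, function(s) mean(s$mask), numeric(1))
  expect_gt(var(bvtv), 0)
  expect_error(generateCohort(1), "n >= 2")
})

test_that("imaged-cohort moduli increase with true bone volume fraction", {
  # structural variation only (fixed mineralization), HR arm, end to end
  coh <- generateCohort(10,
                        ranges = list(plateThickness = c(180, 340),
                                      plateSpacing = c(550, 750),
                                      rodFraction = c(0.05, 0.3)),
                        seed = 9L,
                        baseSpec = phantomSpec(gridSize = 24L, seed = 1L))
  mods <- vapply(coh, function(s) {
    ash <- chaToAsh(bmdToCha(s$hr))
    runProtocol(ash, NULL, modes = "compression",
                keepStates = FALSE)$compression$modulus@modulus
  }, numeric(1))
  bvtv <- vapply(coh, function(s) mean(s$mask), numeric(1))
  expect_gt(cor(mods, bvtv, method = "spearman"), 0.9)
})
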