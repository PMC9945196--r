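test_that("modulus extraction finds slope, window and fallback correctly", {
  eps <- (1:50) * 2e-5
  lin <- data.frame(strain = eps, stress = 1700 * eps)
  r <- extractModulus(lin)
  expect_equal(r@modulus, 1700, tolerance = 1e-12)
  expect_equal(r@window, c(1L, 50L))

  # bilinear: linear to sub-step 25, flat afterwards
  bil <- data.frame(strain = eps,
                    stress = pmin(1700 * eps, 1700 * eps[25]))
  rb <- extractModulus(bil)
  expect_lte(rb@window[2], 25L)
  expect_equal(rb@modulus, 1700, tolerance = 0.005)

  two <- data.frame(strain = c(1e-5, 2e-5), stress = c(0.02, 0.05))
  r2 <- extractModulus(two)
  expect_equal(r2@modulus, 0.03 / 1e-5)
})

test_that("runProtocol recovers E on a homogeneous block and shear modes are symmetric", {
  vol <- ashVolume(c(6, 6, 6), 1.0)
  lawRef <- materialLaw()
  Eref <- lawRef@ECoef * 1.0^lawRef@EExp
  res <- runProtocol(vol, NULL, modes = "compression", bc = "validation",
                     keepStates = FALSE)
  expect_lt(abs(res$compression$modulus@modulus - Eref) / Eref, 0.005)

  resS <- runProtocol(vol, NULL, modes = c("x_shear", "y_shear"),
                      keepStates = FALSE)
  mx <- resS$x_shear$modulus@modulus
  my <- resS$y_shear$modulus@modulus
  expect_lt(abs(mx - my) / mx, 1e-6)
})

test_that("modulus is invariant under rigid translation of the VOI", {
  set.seed(21)
  d <- c(8, 8, 8)
  vals <- array(runif(prod(d), 0.1, 1.2), d)
  mask1 <- array(FALSE, d); mask1[2:5, 2:5, 2:5] <- TRUE
  mask2 <- array(FALSE, d); mask2[4:7, 3:6, 3:6] <- TRUE
  # same VOI content at both positions
  vals2 <- vals
  vals2[4:7, 3:6, 3:6] <- vals[2:5, 2:5, 2:5]
  m1 <- runProtocol(DensityVolume(vals, 150, "ash"), mask1,
                    modes = "compression", keepStates = FALSE)
  m2 <- runProtocol(DensityVolume(vals2, 150, "ash"), mask2,
                    modes = "compression", keepStates = FALSE)
  expect_equal(m1$compression$modulus@modulus, m2$compression$modulus@modulus,
               tolerance = 1e-10)
})

test_that("scaling ash density upward never decreases a modulus", {
  ph <- generatePhantom(phantomSpec(gridSize = 12L, seed = 4L))
  ash <- chaToAsh(bmdToCha(ph$volume))
  up <- DensityVolume(voxelValues(ash) * 1.25, spacing(ash), "ash")
  for (mode in c("compression", "x_shear")) {
    m0 <- runProtocol(ash, NULL, modes = mode, keepStates = FALSE)[[mode]]
    m1 <- runProtocol(up, NULL, modes = mode, keepStates = FALSE)[[mode]]
    expect_gte(m1$modulus@modulus, m0$modulus@modulus)
  }
})

test_that("axially aligned plates are stiffer in compression than rotated ones", {
  aligned <- generatePhantom(phantomSpec(gridSize = 16L, orientation = "x",
                                         rodFraction = 0, seed = 8L))
  rotated <- generatePhantom(phantomSpec(gridSize = 16L, orientation = "z",
                                         rodFraction = 0, seed = 8L))
  run <- function(ph) {
    ash <- chaToAsh(bmdToCha(ph$volume))
    runProtocol(ash, NULL, modes = "compression",
                keepStates = FALSE)$compression$modulus@modulus
  }
  expect_gt(run(aligned), run(rotated))
})

test_that("runProtocol validates units and geometry and writes curves", {
  bmd <- DensityVolume(array(1.2, c(4, 4, 4)), 150, "BMD")
  expect_error(runProtocol(bmd), "unit error")
  ash <- ashVolume(c(4, 4, 4), 0.6)
  expect_error(runProtocol(ash, array(TRUE, c(3, 3, 3))), "geometry")

  res <- runProtocol(ash, NULL, modes = "compression", keepStates = FALSE)
  d <- tempfile()
  paths <- writeCurvesCSV(res, d)
  expect_true(file.exists(file.path(d, "curve_compression.csv")))
  back <- read.csv(file.path(d, "curve_compression.csv"))
  expect_equal(nrow(back), 50)
  expect_equal(back$strain, res$compression$curve$strain)
})
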