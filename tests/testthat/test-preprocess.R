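# Cylinder test volume: high-density shaft in a water background, optionally
# tilted about the y axis.
makeCylinder <- function(d = c(32, 32, 48), radius = 9, tiltDeg = 0,
                         spacing = 300) {
  vals <- array(1.0, d)
  truth <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    cx <- d[1] / 2 + 0.5 + tan(tiltDeg * pi / 180) * (k - d[3] / 2)
    xx <- outer(seq_len(d[1]) - cx, rep(1, d[2]))
    yy <- outer(rep(1, d[1]), seq_len(d[2]) - d[2] / 2 - 0.5)
    disk <- xx^2 + yy^2 <= radius^2
    vals[, , k][disk] <- 1.8
    truth[, , k][disk] <- TRUE
  }
  list(volume = DensityVolume(vals, spacing, "BMD"), truth = truth)
}

test_that("segmentation recovers a cylinder within a one-voxel shell", {
  cyl <- makeCylinder()
  mask <- segmentBone(cyl$volume, 1.4)
  # mask within one dilation of truth and vice versa
  dil <- function(m) {
    out <- m
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
      out <- out | tbfe:::.shift3d(m, o[1], o[2], o[3], FALSE)
    out
  }
  expect_true(all(!mask | dil(cyl$truth)))
  expect_true(all(!cyl$truth | dil(mask)))
})

test_that("segmentation keeps the largest component and rejects empty masks", {
  d <- c(20, 20, 20)
  vals <- array(0, d)
  vals[2:12, 2:12, 2:12] <- 2      # large blob
  vals[16:18, 16:18, 16:18] <- 2   # small blob
  v <- DensityVolume(vals, 150, "BMD")
  mask <- segmentBone(v, 1)
  expect_true(all(mask[2:12, 2:12, 2:12]))
  expect_false(any(mask[16:18, 16:18, 16:18]))
  expect_error(segmentBone(v, 99), "segmentation error")
})

test_that("bone axis is recovered for upright and tilted shafts", {
  spc <- 300
  vs <- voiSpec(tibiaLengthMm = 30)   # 8% site ~ 8 slices at 300 um
  up <- makeCylinder(tiltDeg = 0)
  ax0 <- computeBoneAxis(segmentBone(up$volume, 1.4), vs, spc)
  expect_lt(sqrt(sum((ax0 - c(0, 0, 1))^2)), 1e-3)

  tl <- makeCylinder(tiltDeg = 10)
  ax <- computeBoneAxis(segmentBone(tl$volume, 1.4), vs, spc)
  want <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  expect_lt(acos(min(1, sum(ax * want))) * 180 / pi, 0.5)
  expect_gt(ax[3], 0)   # sign convention

  flat <- array(FALSE, c(10, 10, 12)); flat[3:7, 3:7, 2] <- TRUE
  expect_error(computeBoneAxis(flat, vs, spc), "axis error")
})

test_that("identity alignment reproduces the volume and lattice rotations permute it", {
  set.seed(41)
  d <- c(12, 12, 12)
  # smooth band-limited pattern
  g <- seq(0, 2 * pi, length.out = 12)
  vals <- outer(outer(sin(g), cos(2 * g)), sin(g + 1)) + 2
  v <- DensityVolume(array(vals, d), 200, "BMD")

  idn <- alignAndResample(v, c(0, 0, 1), 200, lanczosA = 3)
  expect_equal(dim(idn), d)
  expect_lt(max(abs(voxelValues(idn) - voxelValues(v))), 1e-6)

  # 90 degree rotation about z maps the lattice onto itself
  rot <- alignAndResample(v, c(0, 0, 1), 200, xHint = c(0, 1, 0),
                          lanczosA = 3)
  ref <- aperm(voxelValues(v), c(2, 1, 3))[, d[1]:1, ]
  expect_lt(max(abs(voxelValues(rot) - ref)), 1e-6)
})

test_that("one combined interpolation pass beats two sequential passes", {
  g <- seq(0, 2 * pi, length.out = 24)
  vals <- outer(outer(sin(2 * g), cos(g)), sin(g)) + 2
  v <- DensityVolume(array(vals, c(24, 24, 24)), 200, "BMD")
  ax <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  two <- alignAndResample(alignAndResample(v, ax, 200, lanczosA = 3),
                          c(-ax[1] * ax[3], 0, 1 - ax[1]^2) /
                            sqrt(ax[1]^2 * ax[3]^2 + (1 - ax[1]^2)^2),
                          200, lanczosA = 3)
  one <- alignAndResample(v, c(0, 0, 1), 200, lanczosA = 3)

  centreCrop <- function(a, n = 10) {
    d <- dim(a); s <- (d - n) %/% 2
    a[s[1] + 1:n, s[2] + 1:n, s[3] + 1:n]
  }
  rmsTwo <- sqrt(mean((centreCrop(voxelValues(two)) -
                         centreCrop(voxelValues(v)))^2))
  rmsOne <- sqrt(mean((centreCrop(voxelValues(one)) -
                         centreCrop(voxelValues(v)))^2))
  expect_lt(rmsOne, rmsTwo)
})

test_that("percent-site VOI selection peels to the target area", {
  spc <- 150
  d <- c(40, 40, 150)
  vals <- array(1.0, d)
  for (k in 1:d[3]) {
    xx <- outer(seq_len(d[1]) - 20.5, rep(1, d[2]))
    yy <- outer(rep(1, d[1]), seq_len(d[2]) - 20.5)
    vals[, , k][xx^2 + yy^2 <= 12^2] <- 1.8
  }
  mask <- segmentBone(DensityVolume(vals, spc, "BMD"), 1.4)

  # the canonical site: 4-6% of a 337.5 mm tibia at 150 um = 45 slices
  vsRef <- voiSpec(tibiaLengthMm = 337.5)
  nRef <- round((vsRef@siteEndPct - vsRef@siteStartPct) / 100 *
                  337.5 * 1000 / 150)
  expect_equal(nRef, 45)

  vs <- voiSpec(tibiaLengthMm = 90, peelPct = 30)  # 4-6% of 90 mm: 12 slices
  voi <- selectVoi(mask, vs, spc)
  zs <- unique(which(voi, arr.ind = TRUE)[, 3])
  expect_equal(length(zs), 12)
  k <- zs[3]
  ratio <- sum(voi[, , k]) / sum(mask[, , k])
  expect_lte(ratio, 0.70 + 1e-9)
  # retained radius ~ r * sqrt(0.7) within one voxel
  rFull <- sqrt(sum(mask[, , k]) / pi)
  rPeel <- sqrt(sum(voi[, , k]) / pi)
  expect_lt(abs(rPeel - rFull * sqrt(0.7)), 1)

  # zero peel returns the mask slab itself
  voi0 <- selectVoi(mask, voiSpec(tibiaLengthMm = 90, peelPct = 0), spc)
  zs0 <- unique(which(voi0, arr.ind = TRUE)[, 3])
  expect_identical(voi0[, , zs0[2]], mask[, , zs0[2]])

  expect_error(selectVoi(mask, voiSpec(tibiaLengthMm = 400), spc),
               "VOI error")
})

test_that("the preprocessing chain is equivariant under lattice rotation", {
  cyl <- makeCylinder(d = c(24, 24, 36), radius = 7, spacing = 300)
  vol <- cyl$volume
  rotVals <- aperm(voxelValues(vol), c(2, 1, 3))[, 24:1, ]
  rot <- DensityVolume(rotVals, 300, "BMD")
  vs <- voiSpec(tibiaLengthMm = 60, peelPct = 30)
  v1 <- selectVoi(segmentBone(vol, 1.4), vs, 300)
  v2 <- selectVoi(segmentBone(rot, 1.4), vs, 300)
  expect_equal(sum(v1), sum(v2))
})
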