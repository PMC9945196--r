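# Connected-component labelling by iterative minimum-label propagation.
# Returns an integer array: 0 = background, components numbered 1..K by
# decreasing size.
.labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  repeat {
    before <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- .shift3d(lab, offs[r, 1], offs[r, 2], offs[r, 3], fill = Inf)
      upd <- mask & (sh < lab)
      lab[upd] <- sh[upd]
    }
    if (identical(before, lab)) break
  }
  ids <- sort(unique(lab[is.finite(lab)]))
  out <- array(0L, d)
  if (length(ids)) {
    m <- match(lab, ids)
    sizes <- tabulate(m[!is.na(m)], nbins = length(ids))
    rank <- order(order(sizes, decreasing = TRUE))
    out[is.finite(lab)] <- rank[m[is.finite(lab)]]
  }
  out
}

# Fill interior cavities: background 6-components not touching the border.
.fillHoles <- function(mask) {
  bg <- .labelComponents(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  border <- setdiff(border, 0L)
  mask | (bg > 0L & !(bg %in% border))
}

#' Threshold-based bone segmentation
#'
#' Simple segmentation stand-in: threshold, keep the largest 26-connected
#' component, fill interior cavities. Dedicated validated tibia-segmentation
#' algorithms are outside this package's scope; this operator is adequate
#' for synthetic phantoms and clean high-contrast scans.
#'
#' @param volume a \linkS4class{DensityVolume}.
#' @param threshold voxel-value threshold (volume units).
#' @return logical bone mask.
#' @export
segmentBone <- function(volume, threshold) {
  stopifnot(is(volume, "DensityVolume"))
  mask <- voxelValues(volume) >= threshold
  if (!any(mask))
    .stopf("segmentation error: empty mask (threshold above the value range?)")
  comp <- .labelComponents(mask, connectivity = 26L)
  .fillHoles(comp == 1L)
}

# Erode one axial slice until its area drops to (1 - peelPct/100) of the
# original; 3x3 cross structuring element per step.
.peelSlice <- function(slice, peelPct) {
  if (peelPct <= 0) return(slice)
  target <- sum(slice) * (1 - peelPct / 100)
  kern <- EBImage::makeBrush(3, shape = "diamond")
  m <- slice * 1
  while (sum(m) > target) {
    m2 <- EBImage::erode(m, kern)
    if (sum(m2) == 0) break
    m <- m2
  }
  m > 0
}

#' Estimate the bone longitudinal axis
#'
#' Applies the configured in-plane peel to each axial slice of the bone mask,
#' restricts to the region proximal to the configured percent site (measured
#' from the most distal mask slice; z is assumed to increase proximally),
#' and returns the principal axis of the retained voxel point cloud, sign
#' fixed so the z component is positive.
#'
#' @param mask logical bone mask.
#' @param spec a \linkS4class{VoiSpec}.
#' @param spacing voxel spacing, micrometres.
#' @return unit 3-vector.
#' @export
computeBoneAxis <- function(mask, spec = voiSpec(), spacing = 150) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  zHas <- which(apply(mask, 3, any))
  if (length(zHas) < 10L)
    .stopf("axis error: mask must span >= 10 slices")
  zmin <- min(zHas)
  siteVox <- round(spec@axisProximalPct / 100 * spec@tibiaLengthMm * 1000 /
                     spacing)
  z0 <- zmin + siteVox
  region <- intersect(zHas, z0:max(zHas))
  if (length(region) < 10L)
    .stopf("axis error: fewer than 10 slices proximal to the %g%% site",
           spec@axisProximalPct)
  peeled <- mask
  peeled[] <- FALSE
  for (k in region)
    peeled[, , k] <- mask[, , k] & .peelSlice(mask[, , k], spec@axisPeelPct)
  pts <- which(peeled, arr.ind = TRUE)
  if (nrow(pts) < 10L || length(unique(pts[, 3])) < 3L)
    .stopf("axis error: degenerate (flat) axis region")
  # line through the per-slice centroids: unbiased for a tilted shaft,
  # unlike a raw principal axis of the voxel cloud, whose slant-cut end
  # faces tip the dominant eigenvector
  zs <- sort(unique(pts[, 3]))
  cx <- vapply(zs, function(k) mean(pts[pts[, 3] == k, 1]), numeric(1))
  cy <- vapply(zs, function(k) mean(pts[pts[, 3] == k, 2]), numeric(1))
  bx <- coef(lm(cx ~ zs))[2L]
  by <- coef(lm(cy ~ zs))[2L]
  v <- c(bx, by, 1)
  v / sqrt(sum(v^2))
}

# Lanczos kernel, window parameter a.
.lanczos <- function(x, a) {
  out <- numeric(length(x))
  nz <- abs(x) < a & abs(x) > 1e-12
  out[abs(x) <= 1e-12] <- 1
  xn <- x[nz]
  out[nz] <- (sin(pi * xn) / (pi * xn)) * (sin(pi * xn / a) / (pi * xn / a))
  out
}

#' Rigidly align a volume to its bone axis and resample isotropically
#'
#' Combines the rotation taking \code{axis} to z (with x steered toward
#' \code{xHint}, e.g. the tibiofibular direction) and the resampling to
#' \code{targetSpacing} into a single windowed-sinc (Lanczos) interpolation
#' pass, so the image suffers one interpolation, not two.
#'
#' @param volume a \linkS4class{DensityVolume}.
#' @param axis unit 3-vector to align with the output z axis.
#' @param targetSpacing output isotropic spacing, micrometres.
#' @param xHint in-plane direction steering the output x axis.
#' @param lanczosA Lanczos window parameter (5 lobes by default; 3 trades
#'   accuracy for speed).
#' @param background fill value for output voxels sampled outside the input.
#' @return a resampled \linkS4class{DensityVolume}.
#' @export
alignAndResample <- function(volume, axis = c(0, 0, 1), targetSpacing = 150,
                             xHint = c(1, 0, 0), lanczosA = 5,
                             background = NULL) {
  stopifnot(is(volume, "DensityVolume"))
  axis <- axis / sqrt(sum(axis^2))
  if (abs(sum(axis^2) - 1) > 1e-8) .stopf("axis must have unit norm")
  ex <- xHint - sum(xHint * axis) * axis
  if (sqrt(sum(ex^2)) < 1e-8) .stopf("xHint is parallel to the axis")
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(axis[2] * ex[3] - axis[3] * ex[2],
          axis[3] * ex[1] - axis[1] * ex[3],
          axis[1] * ex[2] - axis[2] * ex[1])
  R <- rbind(ex, ey, axis)            # rows: output axes in input coords

  vals <- voxelValues(volume)
  d <- dim(vals)
  hIn <- spacing(volume)
  if (targetSpacing <= 0) .stopf("config error: unsupported target spacing")
  if (is.null(background)) background <- min(vals)

  # output grid sized to cover the rotated input box
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3]))) * hIn
  cIn <- d * hIn / 2
  rot <- t(R %*% (t(corners) - cIn))
  extent <- apply(rot, 2, max) - apply(rot, 2, min)
  dOut <- pmax(2L, as.integer(ceiling(extent / targetSpacing)))

  # output voxel centres in input continuous index space (1-based)
  ou <- lapply(1:3, function(k) (seq_len(dOut[k]) - 0.5) * targetSpacing -
                 extent[k] / 2)
  P <- cbind(rep(ou[[1]], times = dOut[2] * dOut[3]),
             rep(rep(ou[[2]], each = dOut[1]), times = dOut[3]),
             rep(ou[[3]], each = dOut[1] * dOut[2]))
  src <- t(crossprod(R, t(P)) + cIn)   # R^T p + centre, micrometres
  f <- sweep(src, 2, hIn, "/") + 0.5   # continuous 1-based voxel index

  a <- as.integer(lanczosA)
  base <- floor(f)
  frac <- f - base
  acc <- numeric(nrow(f))
  wsum <- numeric(nrow(f))
  wAxis <- function(k, m) .lanczos(frac[, k] - m, a)
  inside <- f[, 1] >= 0.5 & f[, 1] <= d[1] + 0.5 &
            f[, 2] >= 0.5 & f[, 2] <= d[2] + 0.5 &
            f[, 3] >= 0.5 & f[, 3] <= d[3] + 0.5
  wx <- lapply((-a + 1L):a, function(m) wAxis(1, m))
  wy <- lapply((-a + 1L):a, function(m) wAxis(2, m))
  wz <- lapply((-a + 1L):a, function(m) wAxis(3, m))
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (mz in seq_len(2L * a)) {
    iz <- clamp(base[, 3] + (mz - a), d[3])
    for (my in seq_len(2L * a)) {
      iy <- clamp(base[, 2] + (my - a), d[2])
      wyz <- wy[[my]] * wz[[mz]]
      off <- (iy - 1) * d[1] + (iz - 1) * d[1] * d[2]
      for (mx in seq_len(2L * a)) {
        w <- wx[[mx]] * wyz
        ix <- clamp(base[, 1] + (mx - a), d[1])
        acc <- acc + w * vals[ix + off]
        wsum <- wsum + w
      }
    }
  }
  out <- acc / wsum
  out[!inside] <- background
  DensityVolume(array(out, dOut), targetSpacing, densityUnits(volume))
}

#' Select the percent-site axial VOI with periosteal peeling
#'
#' Takes the slab between \code{siteStartPct} and \code{siteEndPct} of the
#' tibial length, measured proximally from the most distal mask slice, and
#' peels each axial slice by iterative in-plane erosion until its area is
#' reduced by \code{peelPct} percent.
#'
#' @param mask aligned logical bone mask.
#' @param spec a \linkS4class{VoiSpec}.
#' @param spacing voxel spacing, micrometres.
#' @return logical VOI mask.
#' @export
selectVoi <- function(mask, spec = voiSpec(), spacing = 150) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  zHas <- which(apply(mask, 3, any))
  if (!length(zHas)) .stopf("VOI error: empty mask")
  zmin <- min(zHas)
  L <- spec@tibiaLengthMm * 1000
  s0 <- zmin + round(spec@siteStartPct / 100 * L / spacing)
  n <- round((spec@siteEndPct - spec@siteStartPct) / 100 * L / spacing)
  if (n < 1L)
    .stopf("VOI error: percent-site slab is thinner than one slice")
  slices <- s0:(s0 + n - 1L)
  if (min(slices) < 1L || max(slices) > dim(mask)[3])
    .stopf("VOI error: percent-site slab [%d, %d] lies outside the volume",
           min(slices), max(slices))
  out <- mask
  out[] <- FALSE
  for (k in slices) {
    if (!any(mask[, , k])) next
    out[, , k] <- mask[, , k] & .peelSlice(mask[, , k], spec@peelPct)
  }
  if (!any(out)) .stopf("VOI error: VOI empty after peel")
  out
}
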