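#' Normalize a stress field by its 99th percentile
#'
#' Linear mapping \eqn{\tau(p) = \min(\sigma(p)/P_{99}, 1)}: voxels at or
#' above the 99th percentile of the von Mises field map to exactly 1, the
#' mapping is linear below the cap. The percentile uses the linear
#' interpolation rule (R's default type-7 quantile), computed over the whole
#' supplied field (the full VOI by default; pass a masked subset to cap on
#' bone voxels only).
#'
#' @param field numeric vector or array of per-voxel stresses, MPa.
#' @param prob capping percentile (0.99).
#' @return list with \code{tau} (same shape as \code{field}) and \code{cap}
#'   (the percentile stress, MPa).
#' @examples
#' normalizeStress(rep(2, 10))$tau  # uniform field -> all 1
#' @export
normalizeStress <- function(field, prob = 0.99) {
  v <- as.numeric(field)
  if (!length(v) || all(v == 0))
    .stopf("normalization error: field is empty or all zero")
  cap <- unname(quantile(v, prob, type = 7))
  tau <- pmin(v / cap, 1)
  if (is.array(field)) tau <- array(tau, dim(field))
  list(tau = tau, cap = cap)
}

#' Bone volume fraction from BMD
#'
#' Linear partial-occupancy map
#' \eqn{BVF = clip((\rho_{BMD} - \rho_{marrow})/(\rho_{bone} -
#' \rho_{marrow}), 0, 1)}, a documented stand-in for externally validated
#' BVF mappings.
#'
#' @param volume a \linkS4class{DensityVolume} in BMD g/cc.
#' @param marrowDensity BMD mapping to BVF 0, g/cc.
#' @param boneDensity BMD mapping to BVF 1, g/cc.
#' @return numeric array of per-voxel BVF in [0, 1].
#' @export
bvfFromBmd <- function(volume, marrowDensity = 1.0, boneDensity = 1.82) {
  stopifnot(is(volume, "DensityVolume"))
  if (densityUnits(volume) != "BMD")
    .stopf("unit error: bvfFromBmd expects a BMD volume, got '%s'",
           densityUnits(volume))
  if (!(boneDensity > marrowDensity))
    .stopf("config error: boneDensity must exceed marrowDensity")
  pmin(pmax((voxelValues(volume) - marrowDensity) /
              (boneDensity - marrowDensity), 0), 1)
}

#' Fraction of loaded bone
#'
#' BVF-weighted mean of the normalized stress over trabecular voxels:
#' \deqn{\sum_{p \in B} \tau(p) BVF(p) / \sum_{p \in B} BVF(p)}
#'
#' @param tau normalized stress values (vector or array), in [0, 1].
#' @param bvf per-voxel bone volume fraction, same shape.
#' @param tbMask logical mask of trabecular voxels, same shape.
#' @return scalar in [0, 1].
#' @export
loadedFraction <- function(tau, bvf, tbMask) {
  stopifnot(length(tau) == length(bvf), length(bvf) == length(tbMask))
  w <- as.numeric(bvf)[as.logical(tbMask)]
  t <- as.numeric(tau)[as.logical(tbMask)]
  if (sum(w) <= 0)
    .stopf("undefined-fraction error: zero BVF mass over the Tb mask")
  sum(t * w) / sum(w)
}

#' Trabecular vs marrow stress partition
#'
#' Mean and standard deviation of the voxelwise stress over the trabecular
#' and marrow regions, with a Welch unpaired t-test for the difference. The
#' trabecular mask is typically a BVF threshold at 0.5 (a documented
#' stand-in for dedicated Tb/marrow segmentation algorithms); the partition
#' statistic only needs a reasonable mask.
#'
#' @param field per-voxel stress values (vector or array), MPa.
#' @param tbMask logical; TRUE = trabecular, FALSE = marrow. Same length as
#'   \code{field}.
#' @return A \linkS4class{StressPartition}.
#' @export
partitionStats <- function(field, tbMask) {
  stopifnot(length(field) == length(tbMask))
  f <- as.numeric(field); m <- as.logical(tbMask)
  tb <- f[m]; ma <- f[!m]
  if (!length(tb) || !length(ma))
    .stopf("partition error: both regions must be non-empty")
  tt <- t.test(tb, ma, var.equal = FALSE)
  new("StressPartition",
      tbMean = mean(tb), tbStd = sd(tb),
      marrowMean = mean(ma), marrowStd = sd(ma),
      tStatistic = unname(tt$statistic), pValue = tt$p.value,
      nTb = length(tb), nMarrow = length(ma))
}

#' Stress histogram over a region
#'
#' Voxel counts over equal-width bins spanning [0, cap]; values above the
#' cap land in the last bin, so counts always sum to the region size.
#'
#' @param field per-voxel stress values, MPa.
#' @param mask logical region mask.
#' @param cap upper edge, MPa (default: max of the field).
#' @param nBins number of bins.
#' @return data.frame with bin mid-points and counts.
#' @export
stressHistogram <- function(field, mask = NULL, cap = NULL, nBins = 50L) {
  f <- as.numeric(field)
  if (!is.null(mask)) f <- f[as.logical(mask)]
  if (is.null(cap)) cap <- max(f)
  breaks <- seq(0, cap, length.out = nBins + 1L)
  idx <- pmin(pmax(findInterval(f, breaks, rightmost.closed = TRUE), 1L),
              nBins)
  counts <- tabulate(idx, nbins = nBins)
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             count = counts)
}

#' Map element-wise solver output back onto the voxel grid
#'
#' @param mesh the \linkS4class{HexMesh} the solution was computed on.
#' @param values per-element numeric vector (e.g. von Mises stresses).
#' @param fill value for voxels outside the mesh.
#' @return numeric array with the mesh's grid dimensions.
#' @export
elementsToGrid <- function(mesh, values, fill = NA_real_) {
  stopifnot(length(values) == nElements(mesh))
  out <- array(fill, mesh@gridDim)
  out[mesh@elementToVoxel] <- values
  out
}
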