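# Reference densities for the CHA conversion (g/cc).
D_CHA <- 3.18
D_WATER <- 1.0

# Ash-density affine map coefficients (g/cc).
ASH_INTERCEPT <- 0.0633
ASH_SLOPE <- 0.887

#' Fit the HU-to-BMD calibration line
#'
#' Ordinary least-squares regression of reference densities (g/cc) on CT
#' numbers (HU), as obtained from a tissue-characterization phantom scanned
#' with the study protocol. Phantom-rod values are accepted pre-averaged:
#' one (HU, density) pair per rod.
#'
#' @param hu numeric vector of CT numbers, or a 2-column data.frame
#'   (HU, density_g_cc) as read by \code{\link{readCalibrationTable}}.
#' @param density reference densities, g/cc (omit when \code{hu} is a table).
#' @return A \linkS4class{CalibrationModel}.
#' @examples
#' fitCalibration(c(0, 1000), c(1, 2))
#' @export
fitCalibration <- function(hu, density) {
  if (is.data.frame(hu)) {
    density <- hu[[2L]]
    hu <- hu[[1L]]
  }
  if (length(hu) != length(density))
    .stopf("calibration error: HU and density lengths differ")
  ok <- is.finite(hu) & is.finite(density)
  hu <- hu[ok]; density <- density[ok]
  if (length(hu) < 2L || length(unique(hu)) < 2L)
    .stopf("calibration error: need >= 2 samples with distinct HU values")
  fit <- lm(density ~ hu)
  res <- density - fitted(fit)
  tss <- sum((density - mean(density))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - sum(res^2) / tss)) else 1
  new("CalibrationModel", slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]), rSquared = r2)
}

#' Apply a calibration model to an HU volume
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param volume a \linkS4class{DensityVolume} with units "HU".
#' @return A \linkS4class{DensityVolume} in BMD g/cc.
#' @export
applyCalibration <- function(model, volume) {
  stopifnot(is(model, "CalibrationModel"), is(volume, "DensityVolume"))
  if (densityUnits(volume) != "HU")
    .stopf("unit error: applyCalibration expects an HU volume, got '%s'",
           densityUnits(volume))
  DensityVolume(model@intercept + model@slope * voxelValues(volume),
                spacing(volume), units = "BMD")
}

#' Convert BMD to CHA density
#'
#' Voxelwise \eqn{\rho_{CHA} = (\rho_{BMD} - D_{water})/(D_{CHA} - D_{water})
#' \times D_{CHA}} with \eqn{D_{CHA} = 3.18} g/cc and \eqn{D_{water} = 1}
#' g/cc. Values below water density (fat-rich marrow) map to negative CHA
#' density and are deliberately not clipped here: the material map applies
#' its own floor, and clipping twice would hide calibration faults.
#'
#' @param volume a \linkS4class{DensityVolume} in BMD g/cc.
#' @return A \linkS4class{DensityVolume} in CHA g/cc.
#' @examples
#' v <- DensityVolume(array(1.0, c(2, 2, 2)), 150, "BMD")
#' range(voxelValues(bmdToCha(v)))  # pure water -> 0
#' @export
bmdToCha <- function(volume) {
  stopifnot(is(volume, "DensityVolume"))
  if (densityUnits(volume) != "BMD")
    .stopf("unit error: bmdToCha expects a BMD volume, got '%s'",
           densityUnits(volume))
  vals <- (voxelValues(volume) - D_WATER) / (D_CHA - D_WATER) * D_CHA
  DensityVolume(vals, spacing(volume), units = "CHA")
}

#' Convert CHA density to ash density
#'
#' Voxelwise \eqn{\rho_{ash} = 0.0633 + 0.887 \rho_{CHA}} (g/cc).
#'
#' @param volume a \linkS4class{DensityVolume} in CHA g/cc.
#' @return A \linkS4class{DensityVolume} in ash g/cc.
#' @export
chaToAsh <- function(volume) {
  stopifnot(is(volume, "DensityVolume"))
  if (densityUnits(volume) != "CHA")
    .stopf("unit error: chaToAsh expects a CHA volume, got '%s'",
           densityUnits(volume))
  DensityVolume(ASH_INTERCEPT + ASH_SLOPE * voxelValues(volume),
                spacing(volume), units = "ash")
}

#' Analytic inverses of the density conversions
#'
#' Exact inverses of \code{\link{bmdToCha}} and \code{\link{chaToAsh}},
#' mainly useful for constructing phantoms with prescribed downstream
#' densities and for round-trip checks.
#'
#' @param volume a \linkS4class{DensityVolume} in the source units.
#' @return A \linkS4class{DensityVolume} in the inverted units.
#' @export
chaToBmd <- function(volume) {
  stopifnot(is(volume, "DensityVolume"))
  if (densityUnits(volume) != "CHA")
    .stopf("unit error: chaToBmd expects a CHA volume, got '%s'",
           densityUnits(volume))
  vals <- voxelValues(volume) / D_CHA * (D_CHA - D_WATER) + D_WATER
  DensityVolume(vals, spacing(volume), units = "BMD")
}

#' @rdname chaToBmd
#' @export
ashToCha <- function(volume) {
  stopifnot(is(volume, "DensityVolume"))
  if (densityUnits(volume) != "ash")
    .stopf("unit error: ashToCha expects an ash volume, got '%s'",
           densityUnits(volume))
  DensityVolume((voxelValues(volume) - ASH_INTERCEPT) / ASH_SLOPE,
                spacing(volume), units = "CHA")
}
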