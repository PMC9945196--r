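#' DensityVolume: a 3D scalar density grid
#'
#' Container for a 3D image at isotropic voxel spacing carrying one of the
#' density quantities used along the calibration chain: raw CT numbers
#' (\code{"HU"}), calibrated bone mineral density (\code{"BMD"}, g/cc),
#' calcium-hydroxyapatite equivalent density (\code{"CHA"}, g/cc) or ash
#' density (\code{"ash"}, g/cc). The units tag is updated by every conversion
#' so that a volume can never be pushed through the wrong formula silently.
#'
#' @slot values numeric 3D array of voxel values.
#' @slot spacing isotropic voxel spacing in micrometres.
#' @slot units one of \code{"HU"}, \code{"BMD"}, \code{"CHA"}, \code{"ash"}.
#' @export
setClass("DensityVolume",
  representation(values = "array", spacing = "numeric", units = "character"))

setValidity("DensityVolume", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number (micrometres)")
  if (!(object@units %in% c("HU", "BMD", "CHA", "ash")))
    msg <- c(msg, "units must be one of 'HU', 'BMD', 'CHA', 'ash'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DensityVolume
#'
#' @param values numeric 3D array.
#' @param spacing isotropic voxel spacing in micrometres.
#' @param units units tag; see \linkS4class{DensityVolume}.
#' @return A \linkS4class{DensityVolume}.
#' @examples
#' v <- DensityVolume(array(1, c(4, 4, 4)), spacing = 150, units = "BMD")
#' spacing(v)
#' @export
DensityVolume <- function(values, spacing, units = "HU") {
  new("DensityVolume", values = values, spacing = as.numeric(spacing),
      units = units)
}

#' @describeIn DensityVolume voxel value array
#' @param x,object a DensityVolume
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname DensityVolume
#' @export
setMethod("voxelValues", "DensityVolume", function(x) x@values)

#' @rdname DensityVolume
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname DensityVolume
#' @export
setMethod("spacing", "DensityVolume", function(x) x@spacing)

#' @rdname DensityVolume
#' @export
setGeneric("densityUnits", function(x) standardGeneric("densityUnits"))

#' @rdname DensityVolume
#' @export
setMethod("densityUnits", "DensityVolume", function(x) x@units)

setMethod("dim", "DensityVolume", function(x) dim(x@values))

setMethod("show", "DensityVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityVolume %dx%dx%d @ %.1f um [%s]\n", d[1], d[2], d[3],
              object@spacing, object@units))
  cat(sprintf("  range: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

#' CalibrationModel: HU to BMD linear calibration
#'
#' Ordinary least-squares line mapping CT numbers (HU) to bone mineral
#' density (g/cc), fitted from a density-calibration phantom scan.
#'
#' @slot slope g/cc per HU.
#' @slot intercept g/cc.
#' @slot rSquared coefficient of determination of the fit.
#' @export
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"))

setValidity("CalibrationModel", function(object) {
  msg <- NULL
  if (!is.finite(object@slope) || object@slope <= 0)
    msg <- c(msg, "slope must be positive")
  if (!is.finite(object@rSquared) ||
      object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: BMD = %.6g * HU + %.6g g/cc (r^2 = %.4f)\n",
              object@slope, object@intercept, object@rSquared))
})

#' MaterialLaw: density-to-material parameter configuration
#'
#' Power laws of ash density defining the elastic modulus and the two
#' characteristic stresses of the Swift-Voce hardening curve, plus the fixed
#' hardening constants. Defaults follow the Keyak-family relationships for
#' ash density in g/cc: \eqn{E = 14900 \rho^{1.86}} MPa,
#' \eqn{S_{max} = 102 \rho^{1.8}} MPa, with the saturation stress a fixed
#' fraction of the maximum stress (0.9 by default, i.e. mild post-yield
#' softening, \eqn{R_1 < 0}). Floors keep marrow-valued voxels meshable with
#' negligible but nonzero stiffness, which is what lets the continuum method
#' skip bone/marrow binarization altogether.
#'
#' @slot ECoef,EExp coefficient (MPa) and exponent of the E power law.
#' @slot SmaxCoef,SmaxExp coefficient (MPa) and exponent of the S_max law.
#' @slot SsatRatio S_sat / S_max ratio (dimensionless).
#' @slot EFloor elastic-modulus floor, MPa.
#' @slot SmaxFloor maximum-stress floor, MPa.
#' @slot b Voce saturation rate (dimensionless), 10 by default.
#' @slot R2 Swift linear hardening slope, MPa (0 by default).
#' @slot poisson Poisson's ratio (0.3 by default).
#' @slot epsEl optional fixed yield strain; \code{NA} derives it as S_max/E.
#' @export
setClass("MaterialLaw",
  representation(ECoef = "numeric", EExp = "numeric",
                 SmaxCoef = "numeric", SmaxExp = "numeric",
                 SsatRatio = "numeric",
                 EFloor = "numeric", SmaxFloor = "numeric",
                 b = "numeric", R2 = "numeric", poisson = "numeric",
                 epsEl = "numeric"))

setValidity("MaterialLaw", function(object) {
  msg <- NULL
  if (object@ECoef < 0 || object@SmaxCoef < 0)
    msg <- c(msg, "power-law coefficients must be >= 0")
  if (object@EExp <= 0 || object@SmaxExp <= 0)
    msg <- c(msg, "power-law exponents must be > 0")
  if (object@EFloor <= 0) msg <- c(msg, "EFloor must be > 0")
  if (object@SmaxFloor <= 0) msg <- c(msg, "SmaxFloor must be > 0")
  if (object@b <= 0) msg <- c(msg, "b must be > 0")
  if (object@poisson < 0 || object@poisson >= 0.5)
    msg <- c(msg, "poisson must lie in [0, 0.5)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MaterialLaw
#'
#' @param ECoef,EExp E power law (MPa vs ash density g/cc).
#' @param SmaxCoef,SmaxExp S_max power law (MPa).
#' @param SsatRatio S_sat/S_max; values < 1 give post-yield softening.
#' @param EFloor,SmaxFloor soft-tissue floors (MPa).
#' @param b Voce saturation rate.
#' @param R2 Swift linear hardening slope (MPa).
#' @param poisson Poisson's ratio.
#' @param epsEl optional fixed yield strain (NA: derived as S_max/E).
#' @return A \linkS4class{MaterialLaw}.
#' @export
materialLaw <- function(ECoef = 14900, EExp = 1.86,
                        SmaxCoef = 102, SmaxExp = 1.8,
                        SsatRatio = 0.9,
                        EFloor = 0.01, SmaxFloor = 1e-3,
                        b = 10, R2 = 0, poisson = 0.3, epsEl = NA_real_) {
  new("MaterialLaw", ECoef = ECoef, EExp = EExp, SmaxCoef = SmaxCoef,
      SmaxExp = SmaxExp, SsatRatio = SsatRatio, EFloor = EFloor,
      SmaxFloor = SmaxFloor, b = b, R2 = R2, poisson = poisson, epsEl = epsEl)
}

setMethod("show", "MaterialLaw", function(object) {
  cat(sprintf("MaterialLaw: E = %g*rho^%g MPa (floor %g), Smax = %g*rho^%g MPa,\n",
              object@ECoef, object@EExp, object@EFloor,
              object@SmaxCoef, object@SmaxExp))
  cat(sprintf("  Ssat = %g*Smax, b = %g, R2 = %g, nu = %g\n",
              object@SsatRatio, object@b, object@R2, object@poisson))
})

#' ElementMaterial: per-element constitutive parameters
#'
#' Vectorized container holding, for each mesh element, the elastic modulus
#' and the Swift-Voce hardening parameters derived from its ash density.
#' \code{R1 = Ssat - Smax} by construction; \code{R1 < 0} encodes post-yield
#' softening.
#'
#' @slot E elastic modulus, MPa.
#' @slot Smax maximum (initial yield) stress, MPa.
#' @slot Ssat saturation stress, MPa.
#' @slot epsEl yield strain (S_max/E unless overridden).
#' @slot R1 Voce stress amplitude Ssat - Smax, MPa.
#' @slot R2 Swift linear slope, MPa.
#' @slot b Voce rate.
#' @slot poisson Poisson's ratio (shared scalar).
#' @export
setClass("ElementMaterial",
  representation(E = "numeric", Smax = "numeric", Ssat = "numeric",
                 epsEl = "numeric", R1 = "numeric", R2 = "numeric",
                 b = "numeric", poisson = "numeric"))

setValidity("ElementMaterial", function(object) {
  n <- length(object@E)
  msg <- NULL
  if (any(lengths(list(object@Smax, object@Ssat, object@epsEl, object@R1)) != n))
    msg <- c(msg, "parameter vectors must share one length")
  if (any(object@E <= 0)) msg <- c(msg, "E must be > 0")
  if (any(object@Smax <= 0)) msg <- c(msg, "Smax must be > 0")
  if (any(object@epsEl <= 0)) msg <- c(msg, "epsEl must be > 0")
  if (any(abs(object@R1 - (object@Ssat - object@Smax)) > 1e-9 * pmax(1, object@Smax)))
    msg <- c(msg, "R1 must equal Ssat - Smax")
  if (any(object@b <= 0)) msg <- c(msg, "b must be > 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("length", "ElementMaterial", function(x) length(x@E))

setMethod("show", "ElementMaterial", function(object) {
  cat(sprintf("ElementMaterial: %d element(s), E in [%.4g, %.4g] MPa, nu = %g\n",
              length(object), min(object@E), max(object@E), object@poisson))
})

setMethod("[", "ElementMaterial", function(x, i, j, ..., drop = TRUE) {
  new("ElementMaterial", E = x@E[i], Smax = x@Smax[i], Ssat = x@Ssat[i],
      epsEl = x@epsEl[i], R1 = x@R1[i],
      R2 = if (length(x@R2) > 1) x@R2[i] else x@R2,
      b = if (length(x@b) > 1) x@b[i] else x@b, poisson = x@poisson)
})

#' HexMesh: voxel-conforming hexahedral mesh
#'
#' 8-node hexahedral mesh in one-to-one correspondence with the true voxels
#' of a mask, with shared nodes deduplicated and deterministic numbering
#' (x fastest, then y, then z). Node coordinates are in millimetres.
#'
#' @slot nodeCoords n x 3 matrix, mm.
#' @slot nodeIJK n x 3 integer matrix of node lattice indices (0-based).
#' @slot elements nElem x 8 integer connectivity (VTK hexahedron order).
#' @slot elementToVoxel linear index of each element's voxel in the mask grid.
#' @slot gridDim mask grid dimensions.
#' @slot spacing voxel spacing, micrometres.
#' @slot edgeCount number of unique element edges.
#' @export
setClass("HexMesh",
  representation(nodeCoords = "matrix", nodeIJK = "matrix",
                 elements = "matrix", elementToVoxel = "integer",
                 gridDim = "integer", spacing = "numeric",
                 edgeCount = "numeric"))

setValidity("HexMesh", function(object) {
  msg <- NULL
  if (ncol(object@elements) != 8L) msg <- c(msg, "elements must have 8 columns")
  if (nrow(object@elements) < 1L) msg <- c(msg, "mesh must have >= 1 element")
  if (any(apply(object@elements, 1, anyDuplicated) > 0))
    msg <- c(msg, "each element must reference 8 distinct nodes")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn HexMesh number of elements
#' @param x,object a HexMesh
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' @rdname HexMesh
#' @export
setMethod("nElements", "HexMesh", function(x) nrow(x@elements))

#' @rdname HexMesh
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname HexMesh
#' @export
setMethod("nNodes", "HexMesh", function(x) nrow(x@nodeCoords))

#' @rdname HexMesh
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname HexMesh
#' @export
setMethod("edgeCount", "HexMesh", function(x) x@edgeCount)

#' @rdname HexMesh
#' @export
setMethod("spacing", "HexMesh", function(x) x@spacing)

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d elements, %d nodes, %d unique edges @ %.1f um\n",
              nElements(object), nNodes(object), object@edgeCount,
              object@spacing))
})

#' LoadCase: displacement-controlled loading protocol
#'
#' @slot mode \code{"compression"}, \code{"x_shear"} or \code{"y_shear"}.
#' @slot totalStrain total applied strain (0.001 = 0.1 percent by default).
#' @slot nSubsteps number of uniform displacement sub-steps (50 by default).
#' @slot bc \code{"platen"} (bottom fully fixed, top orthogonal motion
#'   restricted) or \code{"validation"} (lateral constraints released so the
#'   uniaxial closed form holds; compression only).
#' @export
setClass("LoadCase",
  representation(mode = "character", totalStrain = "numeric",
                 nSubsteps = "integer", bc = "character"))

setValidity("LoadCase", function(object) {
  msg <- NULL
  if (!(object@mode %in% c("compression", "x_shear", "y_shear")))
    msg <- c(msg, "mode must be compression, x_shear or y_shear")
  if (object@totalStrain <= 0) msg <- c(msg, "totalStrain must be > 0")
  if (object@nSubsteps < 1L) msg <- c(msg, "nSubsteps must be >= 1")
  if (!(object@bc %in% c("platen", "validation")))
    msg <- c(msg, "bc must be 'platen' or 'validation'")
  if (identical(object@bc, "validation") && object@mode != "compression")
    msg <- c(msg, "validation BCs are defined for compression only")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LoadCase
#'
#' @param mode load mode.
#' @param totalStrain total strain (dimensionless).
#' @param nSubsteps number of sub-steps.
#' @param bc boundary-condition flavour; see \linkS4class{LoadCase}.
#' @return A \linkS4class{LoadCase}.
#' @export
loadCase <- function(mode = c("compression", "x_shear", "y_shear"),
                     totalStrain = 0.001, nSubsteps = 50L, bc = "platen") {
  new("LoadCase", mode = match.arg(mode), totalStrain = totalStrain,
      nSubsteps = as.integer(nSubsteps), bc = bc)
}

setMethod("show", "LoadCase", function(object) {
  cat(sprintf("LoadCase: %s to %.4g strain in %d sub-steps (%s BCs)\n",
              object@mode, object@totalStrain, object@nSubsteps, object@bc))
})

#' SolverSettings: Newton-Raphson and discretization controls
#'
#' @slot forceTol relative force-residual tolerance (0.005).
#' @slot dispTol relative displacement-increment tolerance (0.05).
#' @slot maxNewtonIters Newton iteration cap per sub-step.
#' @slot quadrature \code{"bbar"} (mean-dilatation, default) or \code{"full"}.
#' @slot method \code{"auto"} (elastic fast path when no element yields,
#'   Newton otherwise), \code{"elastic"} or \code{"newton"}.
#' @slot linearSolver \code{"auto"} (sparse Cholesky up to
#'   \code{directLimit} free DOFs, Jacobi-preconditioned conjugate gradients
#'   beyond), \code{"direct"} or \code{"cg"}. Both produce identical
#'   solutions within \code{cgTol}.
#' @slot cgTol relative residual tolerance of the CG solver.
#' @slot cgMaxIters CG iteration cap.
#' @slot directLimit free-DOF count above which "auto" switches to CG.
#' @slot geometricNonlinearity reserved flag; small-strain kinematics are
#'   used throughout (FALSE).
#' @export
setClass("SolverSettings",
  representation(forceTol = "numeric", dispTol = "numeric",
                 maxNewtonIters = "integer", quadrature = "character",
                 method = "character", linearSolver = "character",
                 cgTol = "numeric", cgMaxIters = "integer",
                 directLimit = "integer", geometricNonlinearity = "logical"))

setValidity("SolverSettings", function(object) {
  msg <- NULL
  if (object@forceTol <= 0 || object@forceTol >= 1)
    msg <- c(msg, "forceTol must lie in (0,1)")
  if (object@dispTol <= 0 || object@dispTol >= 1)
    msg <- c(msg, "dispTol must lie in (0,1)")
  if (object@maxNewtonIters < 1L) msg <- c(msg, "maxNewtonIters must be >= 1")
  if (!(object@quadrature %in% c("bbar", "full")))
    msg <- c(msg, "quadrature must be 'bbar' or 'full'")
  if (!(object@method %in% c("auto", "elastic", "newton")))
    msg <- c(msg, "method must be auto, elastic or newton")
  if (!(object@linearSolver %in% c("auto", "direct", "cg")))
    msg <- c(msg, "linearSolver must be auto, direct or cg")
  if (object@cgTol <= 0 || object@cgTol >= 1e-2)
    msg <- c(msg, "cgTol must lie in (0, 1e-2)")
  if (is.null(msg)) TRUE else msg
})

#' Construct SolverSettings
#'
#' @param forceTol,dispTol relative L2 convergence tolerances.
#' @param maxNewtonIters iteration cap per sub-step.
#' @param quadrature \code{"bbar"} or \code{"full"} 2x2x2 Gauss.
#' @param method solve-path selection; see \linkS4class{SolverSettings}.
#' @param linearSolver \code{"auto"}, \code{"direct"} or \code{"cg"}.
#' @param cgTol,cgMaxIters CG controls.
#' @param directLimit free-DOF threshold for the "auto" switch.
#' @param geometricNonlinearity reserved; must be FALSE.
#' @return A \linkS4class{SolverSettings}.
#' @export
solverSettings <- function(forceTol = 0.005, dispTol = 0.05,
                           maxNewtonIters = 30L, quadrature = "bbar",
                           method = "auto", linearSolver = "auto",
                           cgTol = 1e-8, cgMaxIters = 20000L,
                           directLimit = 20000L,
                           geometricNonlinearity = FALSE) {
  new("SolverSettings", forceTol = forceTol, dispTol = dispTol,
      maxNewtonIters = as.integer(maxNewtonIters), quadrature = quadrature,
      method = method, linearSolver = linearSolver, cgTol = cgTol,
      cgMaxIters = as.integer(cgMaxIters),
      directLimit = as.integer(directLimit),
      geometricNonlinearity = geometricNonlinearity)
}

#' SolutionState: converged state at one sub-step
#'
#' @slot displacements n x 3 nodal displacements, mm.
#' @slot stress nElem x 6 centroid stress (xx, yy, zz, xy, yz, zx), MPa.
#' @slot vonMises per-element von Mises stress, MPa.
#' @slot plasticStrain per-element equivalent plastic strain (centroid mean).
#' @slot nodalForces n x 3 assembled internal nodal forces, N.
#' @slot converged logical.
#' @slot substep sub-step index.
#' @slot appliedStrain applied strain at this sub-step.
#' @export
setClass("SolutionState",
  representation(displacements = "matrix", stress = "matrix",
                 vonMises = "numeric", plasticStrain = "numeric",
                 nodalForces = "matrix", converged = "logical",
                 substep = "integer", appliedStrain = "numeric"))

setValidity("SolutionState", function(object) {
  if (any(object@vonMises < -1e-9)) "vonMises must be >= 0" else TRUE
})

setMethod("show", "SolutionState", function(object) {
  cat(sprintf(
    "SolutionState: sub-step %d (strain %.5g), %s, max von Mises %.4g MPa\n",
    object@substep, object@appliedStrain,
    if (object@converged) "converged" else "NOT converged",
    max(object@vonMises)))
})

#' ModulusResult: slope of the linear section of a stress-strain curve
#'
#' @slot modulus MPa.
#' @slot mode load mode.
#' @slot window first and last sub-step index of the linear window.
#' @slot rSquared fit r-squared over the window.
#' @export
setClass("ModulusResult",
  representation(modulus = "numeric", mode = "character",
                 window = "integer", rSquared = "numeric"))

setMethod("show", "ModulusResult", function(object) {
  cat(sprintf("ModulusResult [%s]: %.4g MPa (window %d..%d, r^2 = %.6f)\n",
              object@mode, object@modulus, object@window[1], object@window[2],
              object@rSquared))
})

#' StressPartition: trabecular vs marrow stress statistics
#'
#' @slot tbMean,tbStd mean and sd of von Mises stress over Tb voxels, MPa.
#' @slot marrowMean,marrowStd same over marrow voxels, MPa.
#' @slot tStatistic,pValue Welch unpaired t-test, Tb vs marrow.
#' @slot nTb,nMarrow region voxel counts.
#' @export
setClass("StressPartition",
  representation(tbMean = "numeric", tbStd = "numeric",
                 marrowMean = "numeric", marrowStd = "numeric",
                 tStatistic = "numeric", pValue = "numeric",
                 nTb = "integer", nMarrow = "integer"))

setMethod("show", "StressPartition", function(object) {
  cat(sprintf(
    "StressPartition: Tb %.3g +/- %.3g MPa (n=%d) vs marrow %.3g +/- %.3g MPa (n=%d)\n",
    object@tbMean, object@tbStd, object@nTb,
    object@marrowMean, object@marrowStd, object@nMarrow))
  cat(sprintf("  Welch t = %.3g, p = %.3g\n", object@tStatistic, object@pValue))
})

#' PhantomSpec: parametric plate/rod trabecular phantom
#'
#' Defines a periodic plate network (plate planes containing the z/loading
#' axis when \code{orientation} is "x" or "y") with optional connecting rods,
#' embedded in marrow, specified in BMD units so the full densitometric
#' calibration chain is exercised downstream. Default structural scales sit
#' in the physiologic trabecular range (plate thickness ~250 um, spacing
#' period ~650 um).
#'
#' @slot gridSize 3 integers, voxels.
#' @slot spacing voxel spacing, micrometres.
#' @slot plateSpacing centre-to-centre plate period, micrometres.
#' @slot plateThickness plate thickness, micrometres.
#' @slot rodFraction fraction of candidate inter-plate rod sites filled.
#' @slot boneCha CHA density of bone tissue, g/cc.
#' @slot marrowBmd BMD of marrow background, g/cc.
#' @slot orientation plate normal axis: "x", "y" or "z".
#' @slot seed RNG seed (mandatory; all randomness funnels through it).
#' @export
setClass("PhantomSpec",
  representation(gridSize = "integer", spacing = "numeric",
                 plateSpacing = "numeric", plateThickness = "numeric",
                 rodFraction = "numeric", boneCha = "numeric",
                 marrowBmd = "numeric", orientation = "character",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (length(object@gridSize) != 3L || any(object@gridSize < 1L))
    msg <- c(msg, "gridSize must be 3 positive integers")
  if (object@plateThickness >= object@plateSpacing)
    msg <- c(msg, "plateThickness must be < plateSpacing")
  if (object@rodFraction < 0 || object@rodFraction > 1)
    msg <- c(msg, "rodFraction must lie in [0,1]")
  if (!(object@orientation %in% c("x", "y", "z")))
    msg <- c(msg, "orientation must be x, y or z")
  if (object@boneCha <= 0 || object@boneCha > 3.18)
    msg <- c(msg, "boneCha must lie in (0, 3.18] g/cc")
  if (object@marrowBmd < 0.8 || object@marrowBmd > 1.2)
    msg <- c(msg, "marrowBmd outside physiologic range [0.8, 1.2] g/cc")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PhantomSpec
#'
#' @param gridSize grid dimensions in voxels (scalar recycled to 3).
#' @param spacing voxel spacing, micrometres.
#' @param plateSpacing plate period, micrometres.
#' @param plateThickness plate thickness, micrometres.
#' @param rodFraction fraction of rod sites filled, in [0,1].
#' @param boneCha bone-tissue CHA density, g/cc.
#' @param marrowBmd marrow BMD, g/cc.
#' @param orientation plate normal axis.
#' @param seed RNG seed (mandatory).
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridSize = 48L, spacing = 150, plateSpacing = 650,
                        plateThickness = 250, rodFraction = 0.1,
                        boneCha = 1.2, marrowBmd = 1.0,
                        orientation = "x", seed = 1L) {
  gridSize <- as.integer(rep(gridSize, length.out = 3L))
  new("PhantomSpec", gridSize = gridSize, spacing = spacing,
      plateSpacing = plateSpacing, plateThickness = plateThickness,
      rodFraction = rodFraction, boneCha = boneCha, marrowBmd = marrowBmd,
      orientation = orientation, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %dx%dx%d @ %g um, plates %g/%g um (normal %s), rods %g, seed %d\n",
    object@gridSize[1], object@gridSize[2], object@gridSize[3],
    object@spacing, object@plateThickness, object@plateSpacing,
    object@orientation, object@rodFraction, object@seed))
})

#' ScannerModel: point-spread blurring + noise imaging simulator
#'
#' @slot psfFwhm isotropic Gaussian PSF full width at half maximum, um.
#' @slot noiseStd additive Gaussian noise sd, in the units of the imaged
#'   volume (g/cc for BMD phantoms).
#' @slot outputSpacing reconstruction voxel spacing, um.
#' @export
setClass("ScannerModel",
  representation(psfFwhm = "numeric", noiseStd = "numeric",
                 outputSpacing = "numeric"))

setValidity("ScannerModel", function(object) {
  msg <- NULL
  if (object@psfFwhm < 0) msg <- c(msg, "psfFwhm must be >= 0")
  if (object@noiseStd < 0) msg <- c(msg, "noiseStd must be >= 0")
  if (object@outputSpacing <= 0) msg <- c(msg, "outputSpacing must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ScannerModel
#'
#' @param psfFwhm PSF FWHM, micrometres.
#' @param noiseStd additive noise sd (volume units).
#' @param outputSpacing output voxel spacing, micrometres.
#' @return A \linkS4class{ScannerModel}.
#' @export
scannerModel <- function(psfFwhm = 300, noiseStd = 0.01, outputSpacing = 150) {
  new("ScannerModel", psfFwhm = psfFwhm, noiseStd = noiseStd,
      outputSpacing = outputSpacing)
}

setMethod("show", "ScannerModel", function(object) {
  cat(sprintf("ScannerModel: PSF %g um FWHM, noise sd %g, output %g um\n",
              object@psfFwhm, object@noiseStd, object@outputSpacing))
})

#' VoiSpec: percent-site VOI selection parameters
#'
#' @slot siteStartPct,siteEndPct VOI slab as percent of tibial length from
#'   the distal reference (defaults 4 and 6).
#' @slot peelPct in-plane periosteal peel for the VOI, percent of area (30).
#' @slot axisPeelPct peel used for the bone-axis region (40).
#' @slot axisProximalPct axis region begins proximal to this percent site (8).
#' @slot targetSpacing resampling target, micrometres (150).
#' @slot tibiaLengthMm full tibial length used for percent sites, mm.
#' @export
setClass("VoiSpec",
  representation(siteStartPct = "numeric", siteEndPct = "numeric",
                 peelPct = "numeric", axisPeelPct = "numeric",
                 axisProximalPct = "numeric", targetSpacing = "numeric",
                 tibiaLengthMm = "numeric"))

setValidity("VoiSpec", function(object) {
  msg <- NULL
  if (!(object@siteStartPct >= 0 && object@siteStartPct < object@siteEndPct &&
        object@siteEndPct <= 100))
    msg <- c(msg, "require 0 <= siteStartPct < siteEndPct <= 100")
  if (object@peelPct < 0 || object@peelPct >= 100)
    msg <- c(msg, "peelPct must lie in [0, 100)")
  if (object@axisPeelPct < 0 || object@axisPeelPct >= 100)
    msg <- c(msg, "axisPeelPct must lie in [0, 100)")
  if (object@tibiaLengthMm <= 0) msg <- c(msg, "tibiaLengthMm must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VoiSpec
#'
#' @param siteStartPct,siteEndPct percent-site slab bounds.
#' @param peelPct VOI in-plane peel, percent of area.
#' @param axisPeelPct peel for the axis-estimation region.
#' @param axisProximalPct percent site bounding the axis region distally.
#' @param targetSpacing resampling target, micrometres.
#' @param tibiaLengthMm tibial length, mm (synthetic phantoms supply this).
#' @return A \linkS4class{VoiSpec}.
#' @export
voiSpec <- function(siteStartPct = 4, siteEndPct = 6, peelPct = 30,
                    axisPeelPct = 40, axisProximalPct = 8,
                    targetSpacing = 150, tibiaLengthMm = 337.5) {
  new("VoiSpec", siteStartPct = siteStartPct, siteEndPct = siteEndPct,
      peelPct = peelPct, axisPeelPct = axisPeelPct,
      axisProximalPct = axisProximalPct, targetSpacing = targetSpacing,
      tibiaLengthMm = tibiaLengthMm)
}
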