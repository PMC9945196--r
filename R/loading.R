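#' Build the stress-strain curve of a solved load case
#'
#' One point per sub-step: (applied strain, mean top-surface von Mises
#' stress in MPa).
#'
#' @param mesh a \linkS4class{HexMesh}.
#' @param states list of \linkS4class{SolutionState} from
#'   \code{\link{solveLoadCase}}.
#' @param mode load-mode label.
#' @return data.frame with columns \code{strain} and \code{stress}, with the
#'   mode in attribute \code{"mode"}.
#' @export
stressStrainCurve <- function(mesh, states, mode = "compression") {
  df <- data.frame(
    strain = vapply(states, function(s) s@appliedStrain, numeric(1)),
    stress = vapply(states, function(s) topSurfaceStress(mesh, s), numeric(1)))
  attr(df, "mode") <- mode
  df
}

#' Extract the modulus as the slope of the linear section
#'
#' The "linear section" is operationalized as the longest initial sub-step
#' window whose least-squares line keeps \eqn{r^2 \ge} \code{r2Threshold};
#' the modulus is that line's slope. If no window of at least two points
#' qualifies, the first-two-point secant is returned with a warning.
#'
#' @param curve data.frame from \code{\link{stressStrainCurve}} (columns
#'   \code{strain}, \code{stress}).
#' @param r2Threshold linearity threshold (0.9999 by default).
#' @param mode optional mode label (defaults to the curve attribute).
#' @return A \linkS4class{ModulusResult}.
#' @examples
#' cv <- data.frame(strain = (1:50) * 2e-5, stress = 1700 * (1:50) * 2e-5)
#' extractModulus(cv)  # 1700 MPa, full window
#' @export
extractModulus <- function(curve, r2Threshold = 0.9999, mode = NULL) {
  stopifnot(nrow(curve) >= 2)
  if (is.null(mode)) mode <- attr(curve, "mode")
  if (is.null(mode)) mode <- "compression"
  x <- curve$strain; y <- curve$stress
  n <- length(x)
  best <- NA_integer_
  r2best <- NA_real_
  for (L in n:2) {
    fit <- lm(y[1:L] ~ x[1:L])
    ssr <- sum(resid(fit)^2)
    tss <- sum((y[1:L] - mean(y[1:L]))^2)
    r2 <- if (tss > 0) 1 - ssr / tss else 1
    if (r2 >= r2Threshold) { best <- L; r2best <- r2; break }
  }
  if (is.na(best)) {
    warning("no initial window met the linearity criterion; ",
            "falling back to the first-two-point secant")
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    return(new("ModulusResult", modulus = slope, mode = mode,
               window = c(1L, 2L), rSquared = 1))
  }
  fit <- lm(y[1:best] ~ x[1:best])
  new("ModulusResult", modulus = unname(coef(fit)[2L]), mode = mode,
      window = c(1L, best), rSquared = r2best)
}

#' Run the full three-mode loading protocol
#'
#' Builds the voxel mesh and per-element materials once from the ash-density
#' volume restricted to the VOI mask, then runs the compression, x-shear and
#' y-shear displacement-controlled solves. All three production load cases
#' constrain the same degrees of freedom, so the elastic stiffness is
#' factored once and shared whenever the response stays elastic.
#'
#' The shear "modulus" reported here follows the same construction as the
#' compressive one - the slope of mean top-surface von Mises stress versus
#' applied lateral strain - and is not the classical engineering shear
#' modulus; because the von Mises stress of a shear state carries a factor
#' \eqn{\sqrt 3}, shear moduli routinely exceed compressive ones.
#'
#' @param volume a \linkS4class{DensityVolume} with units "ash".
#' @param voiMask logical array matching the volume; TRUE voxels are meshed.
#' @param law a \linkS4class{MaterialLaw}.
#' @param modes subset of \code{c("compression", "x_shear", "y_shear")}.
#' @param totalStrain,nSubsteps loading protocol (defaults 0.001 and 50).
#' @param settings a \linkS4class{SolverSettings}.
#' @param bc boundary-condition flavour passed to \code{\link{loadCase}}.
#' @param r2Threshold linearity threshold for \code{\link{extractModulus}}.
#' @param keepStates keep the final \linkS4class{SolutionState} per mode.
#' @param dropFloating drop voxel components without a load path to the
#'   bottom surface instead of raising an anchoring error.
#' @return named list per mode with entries \code{curve},
#'   \code{modulus} (a \linkS4class{ModulusResult}) and \code{finalState};
#'   plus \code{mesh} and \code{materials}.
#' @export
runProtocol <- function(volume, voiMask = NULL, law = materialLaw(),
                        modes = c("compression", "x_shear", "y_shear"),
                        totalStrain = 0.001, nSubsteps = 50L,
                        settings = solverSettings(), bc = "platen",
                        r2Threshold = 0.9999, keepStates = TRUE,
                        dropFloating = FALSE) {
  stopifnot(is(volume, "DensityVolume"))
  if (densityUnits(volume) != "ash")
    .stopf("unit error: runProtocol expects an ash-density volume, got '%s'",
           densityUnits(volume))
  if (is.null(voiMask)) voiMask <- array(TRUE, dim(volume))
  if (!all(dim(voiMask) == dim(volume)))
    .stopf("VOI mask geometry does not match the volume")
  mesh <- buildHexMesh(voiMask, spacing(volume), warnDisconnected = FALSE)
  mats <- materialFromAsh(voxelValues(volume)[mesh@elementToVoxel], law)
  fixed <- .resolveAnchoring(mesh, mats, dropFloating)
  mesh <- fixed$mesh
  mats <- fixed$materials
  basis <- .hexBasis(mesh@spacing / 1000, settings@quadrature)
  topElems <- .topLayerElements(mesh)

  # all production load cases constrain the same DOFs, so one elastic
  # stiffness serves every mode; sub-step states are kept lean (the curve
  # needs only the mean top-surface stress per sub-step)
  K <- if (settings@method != "newton")
    .assembleElastic(mesh, mats, settings@quadrature) else NULL

  out <- list(mesh = mesh, materials = mats)
  for (mode in match.arg(modes, several.ok = TRUE)) {
    case <- loadCase(mode, totalStrain = totalStrain, nSubsteps = nSubsteps,
                     bc = bc)
    bcs <- .loadCaseBCs(mesh, case)
    res <- tryCatch({
      lean <- NULL
      if (settings@method != "newton") {
        fin <- .elasticFinal(mesh, mats, settings, bcs, basis, K)
        if (fin$elasticOK || settings@method == "elastic") {
          n <- case@nSubsteps
          meanTop <- mean(fin$q[topElems])
          finalState <- if (keepStates)
            new("SolutionState",
                displacements = matrix(fin$u, ncol = 3, byrow = TRUE),
                stress = fin$stress, vonMises = fin$q,
                plasticStrain = numeric(nElements(mesh)),
                nodalForces = matrix(as.numeric(K %*% fin$u), ncol = 3,
                                     byrow = TRUE),
                converged = TRUE, substep = n,
                appliedStrain = case@totalStrain) else NULL
          lean <- list(curve = data.frame(
            strain = seq_len(n) / n * case@totalStrain,
            stress = seq_len(n) / n * meanTop), final = finalState)
        }
      }
      if (is.null(lean))
        lean <- .solveNewton(mesh, mats, case, settings, bcs, basis,
                             lean = TRUE, topElems = topElems)
      lean
    }, error = function(e) .stopf("[%s] %s", mode, conditionMessage(e)))
    curve <- res$curve
    attr(curve, "mode") <- mode
    out[[mode]] <- list(
      curve = curve,
      modulus = extractModulus(curve, r2Threshold, mode),
      finalState = if (keepStates) res$final else NULL)
  }
  out
}

#' Write per-mode stress-strain curves to CSV
#'
#' @param protocol result of \code{\link{runProtocol}}.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
writeCurvesCSV <- function(protocol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modes <- intersect(names(protocol), c("compression", "x_shear", "y_shear"))
  paths <- character(0)
  for (m in modes) {
    p <- file.path(dir, paste0("curve_", m, ".csv"))
    utils::write.csv(protocol[[m]]$curve, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
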