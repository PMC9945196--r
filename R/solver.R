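# --- element kinematics -----------------------------------------------------
#
# Trilinear 8-node hexahedron on a cube of edge h (mm). Strain ordering is
# Voigt with engineering shears: (exx, eyy, ezz, gxy, gyz, gzx). For the
# axis-aligned cube the Jacobian is diagonal, detJ = (h/2)^3.

.hexBasis <- function(h, quadrature = c("bbar", "full")) {
  quadrature <- match.arg(quadrature)
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g)))
  signs <- cbind(2 * .HEX_OFFSETS[, 1] - 1, 2 * .HEX_OFFSETS[, 2] - 1,
                 2 * .HEX_OFFSETS[, 3] - 1)
  detJ <- (h / 2)^3
  scale <- 2 / h

  Bof <- function(xi, eta, ze) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      sa <- signs[a, ]
      dN <- scale / 8 * c(
        sa[1] * (1 + eta * sa[2]) * (1 + ze * sa[3]),
        sa[2] * (1 + xi  * sa[1]) * (1 + ze * sa[3]),
        sa[3] * (1 + xi  * sa[1]) * (1 + eta * sa[2]))
      c0 <- 3L * (a - 1L)
      B[1, c0 + 1] <- dN[1]
      B[2, c0 + 2] <- dN[2]
      B[3, c0 + 3] <- dN[3]
      B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
      B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
      B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
    }
    B
  }

  Bs <- lapply(seq_len(nrow(gp)), function(i) Bof(gp[i, 1], gp[i, 2], gp[i, 3]))
  B0 <- Bof(0, 0, 0)

  if (quadrature == "bbar") {
    # mean-dilatation: replace the volumetric part of B at every Gauss point
    # by its element average (for the symmetric rule this equals the value
    # at the centroid)
    dil <- function(B) {
      Bd <- matrix(0, 6, 24)
      rowsum3 <- B[1, ] + B[2, ] + B[3, ]
      for (i in 1:3) Bd[i, ] <- rowsum3 / 3
      Bd
    }
    Bdbar <- dil(B0)
    Bs <- lapply(Bs, function(B) B - dil(B) + Bdbar)
  }
  list(B = Bs, B0 = B0, w = rep(detJ, length(Bs)))
}

# Isotropic elastic stiffness for unit E (Voigt, engineering shears).
.elasticDUnit <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Von Mises equivalent stress
#'
#' \deqn{\sigma_{vM} = \sqrt{\tfrac12[(\sigma_{xx}-\sigma_{yy})^2 +
#' (\sigma_{yy}-\sigma_{zz})^2 + (\sigma_{zz}-\sigma_{xx})^2 +
#' 6(\tau_{xy}^2+\tau_{yz}^2+\tau_{zx}^2)]}}
#'
#' @param stress numeric vector of 6 components (xx, yy, zz, xy, yz, zx) or
#'   an n x 6 matrix of such rows, MPa.
#' @return von Mises stress(es), MPa.
#' @examples
#' vonMisesStress(c(5, 0, 0, 0, 0, 0))       # uniaxial -> 5
#' vonMisesStress(c(0, 0, 0, 2, 0, 0))       # pure shear -> 2*sqrt(3)
#' @export
vonMisesStress <- function(stress) {
  s <- if (is.matrix(stress)) stress else matrix(stress, ncol = 6)
  stopifnot(ncol(s) == 6, all(is.finite(s)))
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                     (s[, 3] - s[, 1])^2 +
                     6 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
  if (is.matrix(stress)) out else out[1L]
}

#' Single-element stiffness matrix
#'
#' 24 x 24 stiffness of one cubic trilinear hexahedron, integrated by 2x2x2
#' Gauss quadrature with optional mean-dilatation (B-bar) volumetric
#' treatment (the default, which avoids volumetric locking at nearly
#' incompressible plastic flow). In the elastic case the matrix is symmetric
#' positive-semidefinite with exactly six rigid-body zero-energy modes.
#'
#' @param material an \linkS4class{ElementMaterial} of length 1 (its E and
#'   Poisson ratio define the elastic tangent).
#' @param edgeLength element edge length, mm.
#' @param Dlist optional list of 8 per-Gauss-point 6x6 tangent matrices
#'   overriding the elastic tangent (used by the Newton solver).
#' @param quadrature \code{"bbar"} or \code{"full"}.
#' @return a 24 x 24 symmetric matrix.
#' @export
elementStiffness <- function(material, edgeLength, Dlist = NULL,
                             quadrature = "bbar") {
  stopifnot(is(material, "ElementMaterial"))
  if (edgeLength <= 0) .stopf("material error: edgeLength must be > 0")
  if (material@E[1L] <= 0) .stopf("material error: non-positive modulus")
  basis <- .hexBasis(edgeLength, quadrature)
  if (is.null(Dlist)) {
    D <- material@E[1L] * .elasticDUnit(material@poisson)
    Dlist <- rep(list(D), length(basis$B))
  }
  K <- matrix(0, 24, 24)
  for (g in seq_along(basis$B)) {
    B <- basis$B[[g]]
    K <- K + crossprod(B, Dlist[[g]] %*% B) * basis$w[g]
  }
  (K + t(K)) / 2
}

# --- global assembly --------------------------------------------------------

# 3 dofs per node: node i -> (3i-2, 3i-1, 3i).
.dofMatrix <- function(elements) {
  ne <- nrow(elements)
  dm <- matrix(0L, ne, 24L)
  for (a in 1:8) {
    dm[, 3 * a - 2] <- 3L * elements[, a] - 2L
    dm[, 3 * a - 1] <- 3L * elements[, a] - 1L
    dm[, 3 * a] <- 3L * elements[, a]
  }
  dm
}

# Elastic global stiffness: every element shares one unit stiffness scaled
# by its modulus (same nu for all elements), assembled as triplets in
# element chunks to bound transient memory on large meshes.
.assembleElastic <- function(mesh, materials, quadrature = "bbar",
                             chunk = 30000L) {
  h <- mesh@spacing / 1000
  Kunit <- elementStiffness(materials[1L], h,
                            Dlist = rep(list(.elasticDUnit(materials@poisson)),
                                        8L),
                            quadrature = quadrature)
  dm <- .dofMatrix(mesh@elements)
  il <- rep(1:24, times = 24)
  jl <- rep(1:24, each = 24)
  kvec <- as.vector(Kunit)
  nDof <- 3L * nNodes(mesh)
  ne <- nElements(mesh)
  K <- NULL
  for (s in seq(1L, ne, by = chunk)) {
    e <- min(ne, s + chunk - 1L)
    I <- t(dm[s:e, il, drop = FALSE])
    J <- t(dm[s:e, jl, drop = FALSE])
    X <- kvec %o% materials@E[s:e]
    Kb <- Matrix::sparseMatrix(i = as.vector(I), j = as.vector(J),
                               x = as.vector(X), dims = c(nDof, nDof))
    K <- if (is.null(K)) Kb else K + Kb
  }
  K
}

# Generic elastoplastic tangent assembly (loop over elements); DperElem is a
# list of length nElem, each a list of 8 6x6 tangents.
.assembleTangent <- function(mesh, DperElem, basis) {
  ne <- nElements(mesh)
  dm <- .dofMatrix(mesh@elements)
  blocks <- vector("list", ne)
  for (e in seq_len(ne)) {
    K <- matrix(0, 24, 24)
    for (g in 1:8)
      K <- K + crossprod(basis$B[[g]], DperElem[[e]][[g]] %*% basis$B[[g]]) *
        basis$w[g]
    blocks[[e]] <- K
  }
  I <- t(dm[, rep(1:24, times = 24), drop = FALSE])
  J <- t(dm[, rep(1:24, each = 24), drop = FALSE])
  X <- vapply(blocks, as.vector, numeric(576))
  nDof <- 3L * nNodes(mesh)
  Matrix::sparseMatrix(i = as.vector(I), j = as.vector(J), x = as.vector(X),
                       dims = c(nDof, nDof))
}

# --- anchoring --------------------------------------------------------------

# Voxels 26-connected to the bottom element layer (whose nodes are fixed).
.anchoredVoxels <- function(mesh) {
  d <- mesh@gridDim
  if (nElements(mesh) == prod(d)) return(rep(TRUE, nElements(mesh)))
  mask <- array(FALSE, d)
  mask[mesh@elementToVoxel] <- TRUE
  ks <- arrayInd(mesh@elementToVoxel, d)[, 3]
  kmin <- min(ks)
  reach <- mask
  reach[, , -kmin] <- FALSE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  repeat {
    grown <- reach
    for (r in seq_len(nrow(offs)))
      grown <- grown | .shift3d(reach, offs[r, 1], offs[r, 2], offs[r, 3],
                                FALSE)
    grown <- grown & mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach[mesh@elementToVoxel]
}

# Error on (or optionally drop) voxel components not load-path-connected to
# the fixed bottom surface. Returns possibly rebuilt (mesh, materials).
.resolveAnchoring <- function(mesh, materials, dropFloating) {
  anch <- .anchoredVoxels(mesh)
  if (all(anch)) return(list(mesh = mesh, materials = materials))
  if (!dropFloating)
    .stopf("anchoring error: %d voxel(s) are not connected to the fixed bottom surface, making the stiffness matrix singular; drop them with dropFloating = TRUE or clean the VOI mask",
           sum(!anch))
  warning(sum(!anch), " floating voxel(s) dropped from the mesh")
  d <- mesh@gridDim
  mask <- array(FALSE, d)
  mask[mesh@elementToVoxel[anch]] <- TRUE
  list(mesh = buildHexMesh(mask, mesh@spacing, warnDisconnected = FALSE),
       materials = materials[which(anch)])
}

# --- boundary conditions ----------------------------------------------------

# Prescribed dofs and their values at full load (scale 1); sub-step k uses
# scale k/n. Returns list(dofs, values, height).
.loadCaseBCs <- function(mesh, case) {
  sets <- boundaryNodeSets(mesh, "z")
  z <- mesh@nodeCoords[, 3]
  height <- max(z) - min(z)
  delta <- case@totalStrain * height
  top <- sets$top; bottom <- sets$bottom
  dir <- switch(case@mode, compression = 3L, x_shear = 1L, y_shear = 2L)
  sgn <- if (case@mode == "compression") -1 else 1

  if (case@bc == "platen") {
    dofs <- c(3 * bottom - 2, 3 * bottom - 1, 3 * bottom,
              3 * top - 2, 3 * top - 1, 3 * top)
    vals <- c(rep(0, 3 * length(bottom)), rep(0, 3 * length(top)))
    loaded <- 3 * top - (3 - dir)
    vals[match(loaded, dofs)] <- sgn * delta
  } else {
    # validation mode (compression): axial constraints only, plus the
    # minimal lateral pins removing in-plane rigid modes, so the uniaxial
    # closed-form stress state is admissible
    xy <- mesh@nodeCoords[bottom, 1:2, drop = FALSE]
    ordA <- order(xy[, 2], xy[, 1])
    A <- bottom[ordA[1L]]
    sameY <- bottom[abs(mesh@nodeCoords[bottom, 2] -
                          mesh@nodeCoords[A, 2]) < 1e-12]
    sameY <- setdiff(sameY, A)
    if (!length(sameY))
      .stopf("boundary error: validation BCs need >= 2 bottom nodes on one y-row")
    B <- sameY[which.max(mesh@nodeCoords[sameY, 1])]
    dofs <- c(3 * bottom, 3 * top, 3 * A - 2, 3 * A - 1, 3 * B - 1)
    vals <- c(rep(0, length(bottom)), rep(sgn * delta, length(top)), 0, 0, 0)
  }
  list(dofs = dofs, values = vals, height = height, top = top,
       bottom = bottom)
}

# --- stress evaluation ------------------------------------------------------

# Element centroid stresses for a purely elastic displacement field.
# Returns nElem x 6 matrix.
.elasticCentroidStress <- function(mesh, materials, u, basis) {
  dm <- .dofMatrix(mesh@elements)
  Ue <- matrix(u[dm], nrow = nElements(mesh))
  Dunit <- .elasticDUnit(materials@poisson)
  strain <- Ue %*% t(basis$B0)
  (strain %*% t(Dunit)) * materials@E
}

# --- linear solve helper ----------------------------------------------------

# Jacobi-preconditioned conjugate gradients for SPD sparse systems.
.pcgSolve <- function(A, b, tol = 1e-8, maxIters = 20000L) {
  x <- numeric(length(b))
  r <- b
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  Minv <- 1 / Matrix::diag(A)
  if (any(!is.finite(Minv)))
    .stopf("anchoring error: zero diagonal in the stiffness matrix")
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxIters)) {
    Ap <- as.numeric(A %*% p)
    pAp <- sum(p * Ap)
    if (pAp <= 0)
      .stopf("anchoring error: stiffness matrix not positive definite")
    a <- rz / pAp
    x <- x + a * p
    r <- r - a * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    z <- Minv * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  .stopf("CG did not converge within %d iterations (residual %.3g)",
         maxIters, sqrt(sum(r^2)) / bnorm)
}

.linSolve <- function(Kff, rhs, settings = NULL) {
  useCG <- FALSE
  if (!is.null(settings)) {
    useCG <- settings@linearSolver == "cg" ||
      (settings@linearSolver == "auto" && nrow(Kff) > settings@directLimit)
  }
  if (useCG) {
    .pcgSolve(Kff, as.numeric(rhs), settings@cgTol, settings@cgMaxIters)
  } else {
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                   error = function(e)
                     .stopf("anchoring error: singular stiffness matrix (is every voxel component anchored to the bottom surface?): %s",
                            conditionMessage(e)))
    u <- as.numeric(Matrix::solve(ch, rhs))
    # a semi-definite system (floating voxel component) can slip through the
    # factorization on round-off pivots; verify the solution
    r <- as.numeric(Kff %*% u) - as.numeric(rhs)
    ref <- max(sqrt(sum(as.numeric(rhs)^2)), 1e-300)
    if (any(!is.finite(u)) || sqrt(sum(r^2)) > 1e-6 * ref)
      .stopf("anchoring error: stiffness matrix is numerically singular (is every voxel component anchored to the bottom surface?)")
    u
  }
}

.solveConstrained <- function(K, dofs, vals, settings = NULL) {
  nDof <- nrow(K)
  free <- setdiff(seq_len(nDof), dofs)
  u <- numeric(nDof)
  u[dofs] <- vals
  rhs <- -K[free, dofs, drop = FALSE] %*% vals
  u[free] <- .linSolve(K[free, free, drop = FALSE], rhs, settings)
  u
}

#' One-shot linear elastic solve with arbitrary prescribed displacements
#'
#' Solves the elastic equilibrium problem with the given nodal displacement
#' constraints (no external loads). Useful for patch tests and custom
#' boundary conditions.
#'
#' @param mesh a \linkS4class{HexMesh}.
#' @param materials an \linkS4class{ElementMaterial}, one entry per element.
#' @param nodes integer node indices carrying constraints.
#' @param disp length(nodes) x 3 matrix of prescribed displacements (mm);
#'   NA entries leave that component free.
#' @param quadrature \code{"bbar"} or \code{"full"}.
#' @return A \linkS4class{SolutionState}.
#' @export
solveStatic <- function(mesh, materials, nodes, disp, quadrature = "bbar") {
  stopifnot(is(mesh, "HexMesh"), is(materials, "ElementMaterial"),
            length(materials) == nElements(mesh))
  disp <- as.matrix(disp)
  stopifnot(nrow(disp) == length(nodes), ncol(disp) == 3)
  comp <- which(!is.na(disp), arr.ind = TRUE)
  dofs <- 3L * nodes[comp[, 1]] - (3L - comp[, 2])
  vals <- disp[comp]
  basis <- .hexBasis(mesh@spacing / 1000, quadrature)
  K <- .assembleElastic(mesh, materials, quadrature)
  u <- .solveConstrained(K, dofs, vals)
  stress <- .elasticCentroidStress(mesh, materials, u, basis)
  f <- as.numeric(K %*% u)
  new("SolutionState",
      displacements = matrix(u, ncol = 3, byrow = TRUE),
      stress = stress, vonMises = vonMisesStress(stress),
      plasticStrain = numeric(nElements(mesh)),
      nodalForces = matrix(f, ncol = 3, byrow = TRUE),
      converged = TRUE, substep = 1L, appliedStrain = NA_real_)
}

# --- the displacement-controlled load-case solver ---------------------------

#' Solve a displacement-controlled load case
#'
#' Runs the incremental displacement-controlled solve: the bottom surface is
#' fixed in all directions, the prescribed displacement is applied uniformly
#' over \code{nSubsteps} sub-steps to every top-surface node along the load
#' direction (orthogonal top-node motion restricted), and each sub-step is
#' equilibrated by Newton-Raphson iteration with von Mises plasticity
#' integrated by backward-Euler radial return against the Swift-Voce
#' hardening curve, using the consistent algorithmic tangent.
#'
#' When no element's elastic trial stress at full load exceeds its yield
#' stress, the response is exactly linear in the load factor; the solver
#' then factors the elastic stiffness once and produces all sub-step states
#' by scaling (\code{method = "auto"}). \code{method = "newton"} forces the
#' incremental path.
#'
#' @param mesh a \linkS4class{HexMesh}.
#' @param materials an \linkS4class{ElementMaterial}, one entry per element.
#' @param case a \linkS4class{LoadCase}.
#' @param settings a \linkS4class{SolverSettings}.
#' @param K optional precomputed elastic stiffness (from a previous mode
#'   sharing the same mesh, materials and quadrature).
#' @param dropFloating drop voxel components with no load path to the fixed
#'   bottom surface instead of raising an anchoring error (off by default).
#' @return list of \linkS4class{SolutionState}, one per sub-step.
#' @export
solveLoadCase <- function(mesh, materials, case = loadCase(),
                          settings = solverSettings(), K = NULL,
                          dropFloating = FALSE) {
  stopifnot(is(mesh, "HexMesh"), is(materials, "ElementMaterial"),
            length(materials) == nElements(mesh),
            is(case, "LoadCase"), is(settings, "SolverSettings"))
  fixed <- .resolveAnchoring(mesh, materials, dropFloating)
  if (!identical(fixed$mesh, mesh)) {
    mesh <- fixed$mesh
    materials <- fixed$materials
    K <- NULL
  }
  bcs <- .loadCaseBCs(mesh, case)
  basis <- .hexBasis(mesh@spacing / 1000, settings@quadrature)

  if (settings@method %in% c("auto", "elastic")) {
    if (is.null(K)) K <- .assembleElastic(mesh, materials, settings@quadrature)
    fin <- .elasticFinal(mesh, materials, settings, bcs, basis, K)
    if (fin$elasticOK || settings@method == "elastic") {
      f <- as.numeric(K %*% fin$u)
      n <- case@nSubsteps
      return(lapply(seq_len(n), function(k) {
        s <- k / n
        new("SolutionState",
            displacements = matrix(s * fin$u, ncol = 3, byrow = TRUE),
            stress = s * fin$stress, vonMises = s * fin$q,
            plasticStrain = numeric(nElements(mesh)),
            nodalForces = matrix(s * f, ncol = 3, byrow = TRUE),
            converged = TRUE, substep = as.integer(k),
            appliedStrain = s * case@totalStrain)
      }))
    }
  }
  .solveNewton(mesh, materials, case, settings, bcs, basis)
}

# Full-load elastic solve plus the yield screen: if no element's trial
# von Mises stress exceeds its yield stress at full load, the whole
# displacement-controlled response is exactly linear in the load factor.
.elasticFinal <- function(mesh, materials, settings, bcs, basis, K) {
  u <- .solveConstrained(K, bcs$dofs, bcs$values, settings)
  stress <- .elasticCentroidStress(mesh, materials, u, basis)
  q <- vonMisesStress(stress)
  list(u = u, stress = stress, q = q,
       elasticOK = all(q <= materials@Smax * (1 + 1e-9)))
}

# Stress update by radial return at one Gauss point, vectorized over
# elements. strain/epsP are nE x 6 (engineering shears); alpha length nE.
# Returns list(stress, alphaNew, epsPNew, dgamma, qtrial, sdevTrial).
.radialReturn <- function(materials, strain, epsP, alpha) {
  nu <- materials@poisson
  E <- materials@E
  G <- E / (2 * (1 + nu))
  Dunit <- .elasticDUnit(nu)
  eTrial <- strain - epsP
  sig <- (eTrial %*% t(Dunit)) * E
  p <- (sig[, 1] + sig[, 2] + sig[, 3]) / 3
  s <- sig
  s[, 1:3] <- s[, 1:3] - p
  q <- sqrt(pmax(0, 1.5 * (s[, 1]^2 + s[, 2]^2 + s[, 3]^2 +
                             2 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))))
  idx <- seq_along(E)
  sy0 <- .flowStress(materials, alpha, idx)
  yld <- which(q > sy0 * (1 + 1e-12) & q > 0)
  dg <- numeric(length(E))
  if (length(yld)) {
    # scalar Newton for the consistency condition
    qy <- q[yld]; Gy <- G[yld]; ay <- alpha[yld]
    d <- pmax(0, (qy - sy0[yld]) / (3 * Gy))  # starting guess
    for (it in 1:50) {
      r <- qy - 3 * Gy * d - .flowStress(materials, ay + d, yld)
      dr <- -3 * Gy - .hardeningModulus(materials, ay + d, yld)
      dnew <- d - r / dr
      dnew <- pmax(dnew, 0)
      if (max(abs(dnew - d) / pmax(1e-12, abs(dnew))) < 1e-12) {
        d <- dnew; break
      }
      d <- dnew
    }
    dg[yld] <- d
    fac <- 1 - 3 * G[yld] * d / q[yld]
    s[yld, ] <- s[yld, ] * fac
    sig[yld, ] <- s[yld, ]
    sig[yld, 1:3] <- sig[yld, 1:3] + p[yld]
    # plastic strain increment: normal comps *3/2, engineering shears *3
    scl <- d * 3 / q[yld]
    dep <- s[yld, , drop = FALSE] / fac  # trial deviator
    dep[, 1:3] <- dep[, 1:3] * (scl / 2)
    dep[, 4:6] <- dep[, 4:6] * scl
    epsP[yld, ] <- epsP[yld, , drop = FALSE] + dep
    alpha[yld] <- alpha[yld] + d
  }
  list(stress = sig, epsP = epsP, alpha = alpha, dgamma = dg, qtrial = q,
       sdevTrial = s, pressure = p)
}

# Consistent algorithmic tangent matrices for one Gauss point (list of 6x6
# per element). rr is the output of .radialReturn *before* commit for the
# current iterate.
.consistentTangent <- function(materials, rr) {
  nE <- length(materials@E)
  nu <- materials@poisson
  E <- materials@E
  G <- E / (2 * (1 + nu))
  kap <- E / (3 * (1 - 2 * nu))
  m <- c(1, 1, 1, 0, 0, 0)
  P <- diag(c(1, 1, 1, 0.5, 0.5, 0.5)) - outer(m, m) / 3
  mmT <- outer(m, m)
  Dunit <- .elasticDUnit(nu)
  out <- vector("list", nE)
  for (e in seq_len(nE)) {
    if (rr$dgamma[e] <= 0) {
      out[[e]] <- E[e] * Dunit
    } else {
      q <- rr$qtrial[e]
      dg <- rr$dgamma[e]
      H <- .hardeningModulus(materials, rr$alpha[e], e)
      # unit deviatoric direction of the *trial* stress (tensor norm)
      sdev <- rr$sdevTrial[e, ] / (1 - 3 * G[e] * dg / q)  # undo scaling
      nrm <- sqrt(sum(sdev[1:3]^2) + 2 * sum(sdev[4:6]^2))
      nhat <- sdev / nrm
      theta <- 1 - 3 * G[e] * dg / q
      thetaBar <- 3 * G[e] / (3 * G[e] + H) - 3 * G[e] * dg / q
      out[[e]] <- kap[e] * mmT + 2 * G[e] * theta * P -
        2 * G[e] * thetaBar * outer(nhat, nhat)
    }
  }
  out
}

# Internal force vector from per-gp stresses. stressGp is a list of 8
# nE x 6 matrices.
.internalForce <- function(mesh, stressGp, basis) {
  dm <- .dofMatrix(mesh@elements)
  Fe <- matrix(0, nElements(mesh), 24)
  for (g in 1:8)
    Fe <- Fe + (stressGp[[g]] %*% basis$B[[g]]) * basis$w[g]
  agg <- rowsum(as.vector(Fe), group = as.vector(dm))
  f <- numeric(3L * nNodes(mesh))
  f[as.integer(rownames(agg))] <- agg[, 1]
  f
}

.solveNewton <- function(mesh, materials, case, settings, bcs, basis,
                         lean = FALSE, topElems = NULL) {
  if (lean && is.null(topElems)) topElems <- .topLayerElements(mesh)
  nE <- nElements(mesh)
  nDof <- 3L * nNodes(mesh)
  dm <- .dofMatrix(mesh@elements)
  free <- setdiff(seq_len(nDof), bcs$dofs)

  epsP <- lapply(1:8, function(g) matrix(0, nE, 6))   # committed state
  alpha <- matrix(0, nE, 8)
  u <- numeric(nDof)
  states <- vector("list", case@nSubsteps)
  topStress <- numeric(case@nSubsteps)

  for (k in seq_len(case@nSubsteps)) {
    s <- k / case@nSubsteps
    uPrev <- u
    u[bcs$dofs] <- s * bcs$values
    converged <- FALSE
    lastResid <- NA_real_
    lastDu <- Inf

    for (it in seq_len(settings@maxNewtonIters)) {
      Ue <- matrix(u[dm], nrow = nE)
      stressGp <- vector("list", 8L)
      rrGp <- vector("list", 8L)
      for (g in 1:8) {
        strain <- Ue %*% t(basis$B[[g]])
        rrGp[[g]] <- .radialReturn(materials, strain, epsP[[g]], alpha[, g])
        stressGp[[g]] <- rrGp[[g]]$stress
      }
      fint <- .internalForce(mesh, stressGp, basis)
      resid <- -fint[free]
      refF <- sqrt(sum(fint[bcs$dofs]^2))
      rnorm <- sqrt(sum(resid^2))
      lastResid <- rnorm

      # both L2 criteria (force residual vs reaction norm, last Newton
      # correction vs sub-step displacement increment); a residual far below
      # tolerance alone also terminates, so the first sub-step of a purely
      # elastic response does not pay an extra factorization
      duTotal <- sqrt(sum((u[free] - uPrev[free])^2))
      forceOK <- rnorm <= settings@forceTol * max(refF, 1e-12)
      dispOK <- lastDu <= settings@dispTol * max(duTotal, 1e-15)
      if (forceOK && (dispOK || rnorm <= 1e-3 * settings@forceTol * max(refF, 1e-12))) {
        converged <- TRUE
        break
      }

      DperElem <- vector("list", nE)
      tangGp <- lapply(1:8, function(g) .consistentTangent(materials, rrGp[[g]]))
      for (e in seq_len(nE))
        DperElem[[e]] <- lapply(1:8, function(g) tangGp[[g]][[e]])
      Kt <- .assembleTangent(mesh, DperElem, basis)
      Kff <- Matrix::forceSymmetric(Kt[free, free, drop = FALSE])
      # the elastoplastic tangent can lose definiteness under softening;
      # fall back to a general sparse LU in that case
      du <- tryCatch(as.numeric(Matrix::solve(Matrix::Cholesky(Kff), resid)),
                     error = function(e)
                       tryCatch(as.numeric(Matrix::solve(as(Kff, "generalMatrix"),
                                                         resid)),
                                error = function(e2)
                                  .stopf("anchoring error: singular tangent: %s",
                                         conditionMessage(e2))))
      u[free] <- u[free] + du
      lastDu <- sqrt(sum(du^2))
    }
    if (!converged)
      .stopf("Newton non-convergence at sub-step %d after %d iterations (last residual %.3g)",
             k, settings@maxNewtonIters, lastResid)

    # commit state
    for (g in 1:8) {
      epsP[[g]] <- rrGp[[g]]$epsP
      alpha[, g] <- rrGp[[g]]$alpha
    }
    stress <- Reduce(`+`, stressGp) / 8
    vm <- vonMisesStress(stress)
    if (lean) {
      topStress[k] <- mean(vm[topElems])
      if (k < case@nSubsteps) next
    }
    states[[k]] <- new("SolutionState",
        displacements = matrix(u, ncol = 3, byrow = TRUE),
        stress = stress, vonMises = vm,
        plasticStrain = rowMeans(alpha),
        nodalForces = matrix(fint, ncol = 3, byrow = TRUE),
        converged = TRUE, substep = as.integer(k),
        appliedStrain = s * case@totalStrain)
  }
  if (lean) {
    n <- case@nSubsteps
    return(list(curve = data.frame(
      strain = seq_len(n) / n * case@totalStrain, stress = topStress),
      final = states[[n]]))
  }
  states
}

# Elements whose upper face lies on the top lattice layer.
.topLayerElements <- function(mesh) {
  which(mesh@nodeIJK[mesh@elements[, 5], 3] == max(mesh@nodeIJK[, 3]))
}

#' Mean top-surface von Mises stress of a solution
#'
#' Average of the element-centroid von Mises stress over the volume elements
#' of the top (loaded) surface layer.
#'
#' @param mesh a \linkS4class{HexMesh}.
#' @param state a \linkS4class{SolutionState}.
#' @return scalar MPa.
#' @export
topSurfaceStress <- function(mesh, state) {
  mean(state@vonMises[.topLayerElements(mesh)])
}
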