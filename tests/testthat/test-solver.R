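test_that("element stiffness is symmetric, PSD, with six rigid-body modes", {
  m <- elasticMat(1, 1700)
  K <- elementStiffness(m, 0.15)
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
  expect_gt(min(ev[1:18]), 0)
  # rigid translations and a rigid rotation produce no force
  for (u in list(rep(c(1, 0, 0), 8), rep(c(0, 1, 0), 8), rep(c(0, 0, 1), 8))) {
    expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
  }
  expect_error(elementStiffness(m, -1), "material error")
})

test_that("full-quadrature element stiffness matches the 4x4x4 brute-force oracle", {
  m <- elasticMat(1, 2300, nu = 0.3)
  K <- elementStiffness(m, 0.15, quadrature = "full")
  Ko <- oracleElementK(2300, 0.3, 0.15)
  expect_lt(max(abs(K - Ko)) / max(abs(Ko)), 1e-10)
  ev <- sort(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  evo <- sort(eigen(Ko, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, evo, tolerance = 1e-6)
})

test_that("von Mises stress has its closed forms", {
  expect_equal(vonMisesStress(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(vonMisesStress(c(2, 2, 2, 0, 0, 0)), 0)
  expect_equal(vonMisesStress(c(0, 0, 0, 3, 0, 0)), sqrt(3) * 3)
  expect_equal(vonMisesStress(rbind(c(1, 0, 0, 0, 0, 0),
                                    c(0, 0, 0, 0, 2, 0))),
               c(1, 2 * sqrt(3)))
})

test_that("homogeneous column under validation BCs carries the uniaxial closed form", {
  mesh <- buildHexMesh(array(TRUE, c(4, 4, 6)), 150)
  mats <- elasticMat(nElements(mesh), 1700)
  st <- solveLoadCase(mesh, mats, loadCase("compression", bc = "validation"),
                      solverSettings())
  final <- st[[length(st)]]
  expect_equal(unname(final@vonMises), rep(1.7, nElements(mesh)),
               tolerance = 1e-9)
  # displacements linear in z
  z <- mesh@nodeCoords[, 3]
  uz <- final@displacements[, 3]
  fit <- lm(uz ~ z)
  expect_lt(max(abs(resid(fit))), 1e-12 * max(abs(uz)))
})

test_that("a linear displacement field passes the patch test to 1e-9", {
  mesh <- buildHexMesh(array(TRUE, c(2, 2, 2)), 150)
  mats <- elasticMat(nElements(mesh), 1500)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -5e-4, 2e-4, 1e-4, 4e-4, 6e-4), 3, 3)
  uExact <- mesh@nodeCoords %*% t(A)
  centre <- which(apply(mesh@nodeIJK, 1, function(r) all(r == 1L)))
  bnd <- setdiff(seq_len(nNodes(mesh)), centre)
  sol <- solveStatic(mesh, mats, bnd, uExact[bnd, ])
  expect_lt(max(abs(sol@displacements - uExact)) / max(abs(uExact)), 1e-9)
  # the recovered strain field is the constant symmetric part of A
  eps <- (A + t(A)) / 2
  expect_equal(unname(sol@stress[1, 1:3] - sol@stress[2, 1:3]),
               rep(0, 3), tolerance = 1e-9)
})

test_that("heterogeneous elastic solve matches the dense brute-force oracle", {
  mesh <- buildHexMesh(array(TRUE, c(3, 3, 3)), 150)
  set.seed(7)
  Evec <- runif(nElements(mesh), 500, 5000)
  mats <- elasticMat(nElements(mesh), Evec)
  case <- loadCase("compression", nSubsteps = 2L)
  st <- solveLoadCase(mesh, mats, case,
                      solverSettings(quadrature = "full"))
  bcs <- tbfe:::.loadCaseBCs(mesh, case)
  uo <- oracleDenseElastic(mesh, Evec, 0.3, bcs$dofs, bcs$values)
  scale <- max(abs(uo))
  expect_lt(max(abs(st[[2]]@displacements - uo)) / scale, 1e-8)
  # the CG route gives the same answer within its tolerance
  stCG <- solveLoadCase(mesh, mats, case,
                        solverSettings(quadrature = "full",
                                       linearSolver = "cg", cgTol = 1e-12))
  expect_lt(max(abs(stCG[[2]]@displacements - uo)) / scale, 1e-8)
})

test_that("elastic response scales linearly with the applied strain", {
  mesh <- buildHexMesh(array(TRUE, c(3, 3, 4)), 150)
  set.seed(9)
  mats <- elasticMat(nElements(mesh), runif(nElements(mesh), 800, 4000))
  s1 <- solveLoadCase(mesh, mats, loadCase("compression", totalStrain = 5e-4,
                                           nSubsteps = 2L), solverSettings())
  s2 <- solveLoadCase(mesh, mats, loadCase("compression", totalStrain = 1e-3,
                                           nSubsteps = 2L), solverSettings())
  expect_equal(2 * s1[[2]]@displacements, s2[[2]]@displacements,
               tolerance = 1e-10)
  expect_equal(2 * s1[[2]]@vonMises, s2[[2]]@vonMises, tolerance = 1e-10)
})

test_that("reaction forces on the bottom balance the top forces", {
  mesh <- buildHexMesh(array(TRUE, c(4, 4, 4)), 150)
  set.seed(2)
  mats <- elasticMat(nElements(mesh), runif(nElements(mesh), 500, 3000))
  for (mode in c("compression", "x_shear")) {
    st <- solveLoadCase(mesh, mats, loadCase(mode, nSubsteps = 1L),
                        solverSettings())
    bs <- boundaryNodeSets(mesh, "z")
    fb <- colSums(st[[1]]@nodalForces[bs$bottom, ])
    ft <- colSums(st[[1]]@nodalForces[bs$top, ])
    expect_lt(max(abs(fb + ft)) / max(abs(ft)), 0.005)
  }
})

test_that("prescribed nodes carry exactly their prescribed displacement", {
  mesh <- buildHexMesh(array(TRUE, c(3, 3, 3)), 150)
  mats <- elasticMat(nElements(mesh), 2000)
  case <- loadCase("x_shear", nSubsteps = 2L)
  st <- solveLoadCase(mesh, mats, case, solverSettings())
  bs <- boundaryNodeSets(mesh, "z")
  height <- max(mesh@nodeCoords[, 3]) - min(mesh@nodeCoords[, 3])
  expect_equal(unname(st[[2]]@displacements[bs$top, 1]),
               rep(0.001 * height, length(bs$top)))
  expect_equal(unname(st[[2]]@displacements[bs$top, 2:3]),
               matrix(0, length(bs$top), 2))
  expect_equal(unname(st[[2]]@displacements[bs$bottom, ]),
               matrix(0, length(bs$bottom), 3))
})

test_that("single-element uniaxial loading beyond yield follows the hardening curve", {
  # a 1x1x2 homogeneous column responds like a single element; hardening
  # and softening saturation stresses are both exercised
  for (Ssat in c(6, 4)) {
    mesh <- buildHexMesh(array(TRUE, c(1, 1, 2)), 150)
    mats <- plasticMat(2, E = 1000, Smax = 5, Ssat = Ssat, b = 10)
    case <- loadCase("compression", totalStrain = 0.02, nSubsteps = 50L,
                     bc = "validation")
    st <- solveLoadCase(mesh, mats, case, solverSettings(method = "newton"))
    fe <- vapply(st, function(s) s@vonMises[1], numeric(1))
    ref <- oracle1D(1000, 5, Ssat, 10, (1:50) / 50 * 0.02)
    expect_lt(max(abs(fe - ref) / ref), 0.005)
    expect_gt(max(st[[50]]@plasticStrain), 0)
  }
})

test_that("halving the sub-step size leaves the extracted modulus unchanged", {
  mesh <- buildHexMesh(array(TRUE, c(2, 2, 3)), 150)
  mats <- plasticMat(nElements(mesh), E = 1000, Smax = 1.2, Ssat = 1.4)
  run <- function(n) {
    st <- solveLoadCase(mesh, mats,
                        loadCase("compression", totalStrain = 0.003,
                                 nSubsteps = n),
                        solverSettings(method = "newton"))
    extractModulus(stressStrainCurve(mesh, st))@modulus
  }
  m50 <- run(50L); m100 <- run(100L)
  expect_lt(abs(m50 - m100) / m50, 0.001)
})

test_that("unanchored meshes and Newton stalls raise diagnostic errors", {
  mask <- array(FALSE, c(3, 3, 4))
  mask[, , 1:2] <- TRUE
  mask[2, 2, 4] <- TRUE   # floating voxel above a 2-layer slab
  mesh <- suppressWarnings(buildHexMesh(mask, 150))
  mats <- elasticMat(nElements(mesh), 1000)
  expect_error(solveLoadCase(mesh, mats, loadCase("compression"),
                             solverSettings()),
               "anchoring error")
  # with dropFloating the slab alone is solved
  expect_warning(
    st <- solveLoadCase(mesh, mats, loadCase("compression", nSubsteps = 1L),
                        solverSettings(), dropFloating = TRUE),
    "dropped")
  expect_length(st[[1]]@vonMises, 18)   # 3x3x2 slab

  mesh2 <- buildHexMesh(array(TRUE, c(1, 1, 2)), 150)
  mats2 <- plasticMat(2, E = 1000, Smax = 2, Ssat = 2.4)
  expect_error(
    solveLoadCase(mesh2, mats2,
                  loadCase("compression", totalStrain = 0.02,
                           nSubsteps = 2L, bc = "validation"),
                  solverSettings(method = "newton", maxNewtonIters = 1L)),
    "non-convergence")
})
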