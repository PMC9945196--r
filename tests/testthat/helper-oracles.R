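# Independent oracles used to pin expected values. These deliberately share
# no code with the package: their own quadrature, their own dense assembly,
# their own stress update, base-R solves throughout.

# 4-point Gauss-Legendre rule on [-1, 1].
.gl4 <- list(
  x = c(-0.8611363115940526, -0.3399810435848563,
        0.3399810435848563, 0.8611363115940526),
  w = c(0.3478548451374538, 0.6521451548625461,
        0.6521451548625461, 0.3478548451374538))

# VTK hexahedron corner signs (matches the package's node ordering so DOFs
# line up, which is the only shared convention).
.oracleSigns <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
                      c(-1, -1, 1, 1, -1, -1, 1, 1),
                      c(-1, -1, -1, -1, 1, 1, 1, 1))

oracleB <- function(xi, eta, ze, h) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    s <- .oracleSigns[a, ]
    dN <- (2 / h) / 8 * c(s[1] * (1 + eta * s[2]) * (1 + ze * s[3]),
                          s[2] * (1 + xi * s[1]) * (1 + ze * s[3]),
                          s[3] * (1 + xi * s[1]) * (1 + eta * s[2]))
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[1]; B[2, c0 + 2] <- dN[2]; B[3, c0 + 3] <- dN[3]
    B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
    B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
    B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
  }
  B
}

oracleD <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Brute-force element stiffness at 4x4x4 quadrature (full integration).
oracleElementK <- function(E, nu, h) {
  D <- oracleD(E, nu)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    B <- oracleB(.gl4$x[i], .gl4$x[j], .gl4$x[k], h)
    K <- K + t(B) %*% D %*% B * .gl4$w[i] * .gl4$w[j] * .gl4$w[k] * detJ
  }
  K
}

# Dense elastic solve with explicit constraint elimination (base solve()).
oracleDenseElastic <- function(mesh, Evec, nu, consDofs, consVals) {
  h <- mesh@spacing / 1000
  nDof <- 3 * nNodes(mesh)
  K <- matrix(0, nDof, nDof)
  for (e in seq_len(nElements(mesh))) {
    Ke <- oracleElementK(Evec[e], nu, h)
    dofs <- as.vector(t(cbind(3 * mesh@elements[e, ] - 2,
                              3 * mesh@elements[e, ] - 1,
                              3 * mesh@elements[e, ])))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  free <- setdiff(seq_len(nDof), consDofs)
  u <- numeric(nDof)
  u[consDofs] <- consVals
  u[free] <- solve(K[free, free], -K[free, consDofs] %*% consVals)
  matrix(u, ncol = 3, byrow = TRUE)
}

# --- scalar and Gauss-point elastoplastic oracles ---------------------------

# 1-D strain-driven elastoplastic response with the exponential-saturation
# flow stress, integrated sub-step by sub-step via uniroot on the
# consistency condition.
oracle1D <- function(E, Smax, Ssat, b, strains) {
  syf <- function(a) Smax + (Ssat - Smax) * (1 - exp(-b * a))
  alpha <- 0
  out <- numeric(length(strains))
  for (k in seq_along(strains)) {
    e <- strains[k]
    if (E * (e - alpha) > syf(alpha)) {
      da <- uniroot(function(d) E * (e - alpha - d) - syf(alpha + d),
                    c(0, e), tol = 1e-15)$root
      alpha <- alpha + da
    }
    out[k] <- E * (e - alpha)
  }
  out
}

# Radial-return stress update at one Gauss point (engineering shears),
# consistency condition solved by uniroot.
oracleStressUpdate <- function(strain, epsP, alpha, E, nu, Smax, Ssat, b) {
  G <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  eel <- strain - epsP
  sig <- c(lam * sum(eel[1:3]) + 2 * G * eel[1:3], G * eel[4:6])
  p <- mean(sig[1:3])
  s <- sig - c(p, p, p, 0, 0, 0)
  q <- sqrt(1.5 * (sum(s[1:3]^2) + 2 * sum(s[4:6]^2)))
  syf <- function(a) Smax + (Ssat - Smax) * (1 - exp(-b * a))
  if (q <= syf(alpha) || q == 0)
    return(list(stress = sig, epsP = epsP, alpha = alpha))
  dg <- uniroot(function(d) q - 3 * G * d - syf(alpha + d),
                c(0, q / (3 * G)), tol = 1e-16)$root
  fac <- 1 - 3 * G * dg / q
  sNew <- s * fac
  dep <- numeric(6)
  dep[1:3] <- 1.5 * dg * s[1:3] / q
  dep[4:6] <- 3 * dg * s[4:6] / q
  list(stress = sNew + c(p, p, p, 0, 0, 0), epsP = epsP + dep,
       alpha = alpha + dg)
}

# Dense incremental Newton solve with finite-difference tangents, full
# 2x2x2 integration, explicit elimination. mats: list with vectors E, Smax,
# Ssat, b (per element), scalar nu. Returns displacements and element-mean
# stresses at the final sub-step.
oracleDenseNewton <- function(mesh, mats, consDofs, consValsFull, nSub,
                              tol = 1e-11, fdh = 1e-9) {
  h <- mesh@spacing / 1000
  g <- 1 / sqrt(3)
  gps <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  Bs <- lapply(1:8, function(i) oracleB(gps[i, 1], gps[i, 2], gps[i, 3], h))
  w <- (h / 2)^3
  nE <- nElements(mesh)
  nDof <- 3 * nNodes(mesh)
  dofOf <- function(e) as.vector(t(cbind(3 * mesh@elements[e, ] - 2,
                                         3 * mesh@elements[e, ] - 1,
                                         3 * mesh@elements[e, ])))
  free <- setdiff(seq_len(nDof), consDofs)
  u <- numeric(nDof)
  epsP <- array(0, c(nE, 8, 6))
  alpha <- matrix(0, nE, 8)

  for (k in seq_len(nSub)) {
    u[consDofs] <- (k / nSub) * consValsFull
    for (it in 1:60) {
      fint <- numeric(nDof)
      K <- matrix(0, nDof, nDof)
      trial <- vector("list", nE)
      for (e in seq_len(nE)) {
        dofs <- dofOf(e)
        ue <- u[dofs]
        st <- vector("list", 8)
        Ke <- matrix(0, 24, 24)
        fe <- numeric(24)
        for (gp in 1:8) {
          B <- Bs[[gp]]
          eps <- as.vector(B %*% ue)
          st[[gp]] <- oracleStressUpdate(eps, epsP[e, gp, ], alpha[e, gp],
                                         mats$E[e], mats$nu, mats$Smax[e],
                                         mats$Ssat[e], mats$b[e])
          fe <- fe + as.vector(t(B) %*% st[[gp]]$stress) * w
          Dfd <- matrix(0, 6, 6)
          for (c6 in 1:6) {
            ep <- eps; ep[c6] <- ep[c6] + fdh
            em <- eps; em[c6] <- em[c6] - fdh
            sp <- oracleStressUpdate(ep, epsP[e, gp, ], alpha[e, gp],
                                     mats$E[e], mats$nu, mats$Smax[e],
                                     mats$Ssat[e], mats$b[e])$stress
            sm <- oracleStressUpdate(em, epsP[e, gp, ], alpha[e, gp],
                                     mats$E[e], mats$nu, mats$Smax[e],
                                     mats$Ssat[e], mats$b[e])$stress
            Dfd[, c6] <- (sp - sm) / (2 * fdh)
          }
          Ke <- Ke + t(B) %*% Dfd %*% B * w
        }
        trial[[e]] <- st
        fint[dofs] <- fint[dofs] + fe
        K[dofs, dofs] <- K[dofs, dofs] + Ke
      }
      r <- -fint[free]
      ref <- sqrt(sum(fint[consDofs]^2))
      if (sqrt(sum(r^2)) <= tol * max(ref, 1e-12)) break
      u[free] <- u[free] + solve(K[free, free], r)
    }
    for (e in seq_len(nE)) for (gp in 1:8) {
      epsP[e, gp, ] <- trial[[e]][[gp]]$epsP
      alpha[e, gp] <- trial[[e]][[gp]]$alpha
    }
  }
  stress <- t(vapply(seq_len(nE), function(e)
    Reduce(`+`, lapply(trial[[e]], `[[`, "stress")) / 8, numeric(6)))
  list(displacements = matrix(u, ncol = 3, byrow = TRUE), stress = stress,
       alpha = rowMeans(alpha))
}

oracleVonMises <- function(s) {
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                (s[, 3] - s[, 1])^2 + 6 * rowSums(s[, 4:6, drop = FALSE]^2)))
}

# Ordinary least squares by the normal equations.
oracleOLS <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))  # (intercept, slope)
}

# Type-7 (linear interpolation) percentile by explicit sorting.
oraclePercentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  pos <- (n - 1) * p + 1
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# ICC forms from stats::aov mean squares (independent ANOVA route).
oracleICC <- function(x, y, form) {
  n <- length(x)
  df <- data.frame(value = c(x, y),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  av <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  msr <- av["subject", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  if (form == "A1") (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  else (msr - mse) / (msr + mse)
}
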