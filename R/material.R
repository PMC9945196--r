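#' Map ash density to elastoplastic material parameters
#'
#' Evaluates the configured power laws of ash density for the elastic
#' modulus and the Swift-Voce characteristic stresses, with soft-tissue
#' floors so that every voxel (marrow included) remains meshable: the
#' continuum formulation deliberately assigns material to all voxels instead
#' of binarizing bone from marrow. Negative densities are treated as zero
#' before the power law, then floored.
#'
#' The yield strain defaults to \code{epsEl = Smax/E} (the strain where the
#' linear limb meets the plastic limb of the bilinear-to-plastic curve)
#' unless the law fixes it. \code{R1 = Ssat - Smax} (negative for softening),
#' \code{R2} and \code{b} come from the law.
#'
#' @param rhoAsh numeric vector of ash densities, g/cc (one per element).
#' @param law a \linkS4class{MaterialLaw}.
#' @return An \linkS4class{ElementMaterial} of the same length.
#' @examples
#' m <- materialFromAsh(c(0, 0.5, 1.0), materialLaw())
#' m@E  # floor, then increasing with density
#' @export
materialFromAsh <- function(rhoAsh, law = materialLaw()) {
  stopifnot(is(law, "MaterialLaw"))
  if (any(!is.finite(rhoAsh)))
    .stopf("value error: non-finite ash density")
  r <- pmax(rhoAsh, 0)
  E <- pmax(law@EFloor, law@ECoef * r^law@EExp)
  Smax <- pmax(law@SmaxFloor, law@SmaxCoef * r^law@SmaxExp)
  Ssat <- law@SsatRatio * Smax
  epsEl <- if (is.finite(law@epsEl)) rep(law@epsEl, length(r)) else Smax / E
  new("ElementMaterial", E = E, Smax = Smax, Ssat = Ssat, epsEl = epsEl,
      R1 = Ssat - Smax, R2 = rep(law@R2, length(r)),
      b = rep(law@b, length(r)), poisson = law@poisson)
}

#' Swift-Voce stress-strain law
#'
#' Total-strain stress response of one material: linear \eqn{E\varepsilon}
#' up to the yield strain \eqn{\varepsilon_{el}}, then the mixed Swift-Voce
#' hardening curve
#' \deqn{S(\varepsilon) = S_{max} + R_1(1 - e^{-b(\varepsilon -
#'   \varepsilon_{el})}) + R_2(\varepsilon - \varepsilon_{el})}
#' which equals \eqn{S_{max}} at yield and approaches \eqn{S_{sat}}
#' asymptotically (from above when \eqn{R_1 < 0}, i.e. softening). The curve
#' is continuous everywhere and smooth except at the yield point.
#'
#' @param mat an \linkS4class{ElementMaterial}; length 1, or matching
#'   \code{eps}.
#' @param eps total strain(s), >= 0.
#' @param i element index when \code{mat} holds several elements.
#' @return stress in MPa, same length as \code{eps}.
#' @examples
#' m <- materialFromAsh(1.0, materialLaw())
#' swiftVoceStress(m, m@epsEl)  # = Smax
#' @export
swiftVoceStress <- function(mat, eps, i = 1L) {
  stopifnot(is(mat, "ElementMaterial"), all(eps >= 0))
  m <- if (length(mat) > 1L) mat[i] else mat
  el <- eps <= m@epsEl
  out <- numeric(length(eps))
  out[el] <- m@E * eps[el]
  d <- eps[!el] - m@epsEl
  out[!el] <- m@Smax + m@R1 * (1 - exp(-m@b * d)) + m@R2 * d
  out
}

#' Tangent modulus of the Swift-Voce law
#'
#' Analytic derivative of \code{\link{swiftVoceStress}} with respect to total
#' strain: \eqn{E} below yield, \eqn{R_1 b e^{-b(\varepsilon -
#' \varepsilon_{el})} + R_2} above. One-sided at the yield point (the value
#' for \code{eps == epsEl} is the elastic branch).
#'
#' @inheritParams swiftVoceStress
#' @return tangent modulus in MPa.
#' @export
tangentModulus <- function(mat, eps, i = 1L) {
  stopifnot(is(mat, "ElementMaterial"), all(eps >= 0))
  m <- if (length(mat) > 1L) mat[i] else mat
  el <- eps <= m@epsEl
  out <- numeric(length(eps))
  out[el] <- m@E
  out[!el] <- m@R1 * m@b * exp(-m@b * (eps[!el] - m@epsEl)) + m@R2
  out
}

# Flow stress as a function of equivalent plastic strain alpha:
# sigma_y(alpha) = S(epsEl + alpha). Vectorized over elements.
.flowStress <- function(mat, alpha, idx) {
  mat@Smax[idx] + mat@R1[idx] * (1 - exp(-mat@b[idx] * alpha)) +
    mat@R2[idx] * alpha
}

# Hardening modulus d sigma_y / d alpha.
.hardeningModulus <- function(mat, alpha, idx) {
  mat@R1[idx] * mat@b[idx] * exp(-mat@b[idx] * alpha) + mat@R2[idx]
}
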