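# Construct an ElementMaterial directly, bypassing the density laws, so
# tests can pin E / yield parameters exactly.
elasticMat <- function(n, E, nu = 0.3, Smax = 1e6) {
  new("ElementMaterial", E = rep(E, length.out = n), Smax = rep(Smax, n),
      Ssat = rep(Smax, n), epsEl = rep(Smax, n) / rep(E, length.out = n),
      R1 = rep(0, n), R2 = rep(0, n), b = rep(10, n), poisson = nu)
}

plasticMat <- function(n, E, Smax, Ssat, b = 10, nu = 0.3) {
  new("ElementMaterial", E = rep(E, n), Smax = rep(Smax, n),
      Ssat = rep(Ssat, n), epsEl = rep(Smax / E, n),
      R1 = rep(Ssat - Smax, n), R2 = rep(0, n), b = rep(b, n), poisson = nu)
}

# Uniform-density ash volume helper.
ashVolume <- function(dims, value, spacing = 150) {
  DensityVolume(array(value, dims), spacing, "ash")
}
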