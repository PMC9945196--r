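# tbfe: nonlinear continuum finite-element analysis of trabecular bone strength from CT

Osteoporotic fracture risk is driven not only by how much mineral a bone
contains but by how the trabecular (Tb) micro-network distributes it. At the
resolution of clinical CT, individual trabeculae are only partially
resolved, so the classical micro-FE recipe — binarize bone from marrow, mesh
the bone phase, assign one modulus — discards exactly the partial-volume
information the scan still carries. `tbfe` implements the alternative
*continuum* approach: every voxel of a calibrated density volume becomes an
8-node hexahedral element whose nonlinear material parameters follow from
its ash density, marrow included, and Tb strength is read off a simulated
displacement-controlled loading experiment. Because no binarization step is
involved, the derived strength measures transfer well between CT scanners
with different spatial resolution — the package ships a two-scanner phantom
simulator and the reproducibility statistics (Pearson r, ICC) to quantify
exactly that.

It is aimed at researchers in quantitative musculoskeletal imaging who want
an inspectable, fully scripted re-implementation of the method with a
verifiable solver core.

## Method

1. **Densitometry.** CT numbers are calibrated to BMD with an OLS line
   fitted to a tissue-characterization phantom scan, then converted
   voxelwise to calcium-hydroxyapatite density and ash density:

       rho_CHA = (rho_BMD - D_water) / (D_CHA - D_water) * D_CHA,
       rho_ash = 0.0633 + 0.887 * rho_CHA

   with D_CHA = 3.18 g/cc and D_water = 1 g/cc.

2. **Material model.** Per element, E, S_max and S_sat are power laws of
   ash density (Keyak-family defaults, `materialLaw()`), with Poisson ratio
   0.3 and a mixed Swift–Voce hardening curve beyond the yield strain
   eps_el = S_max/E:

       S(eps) = S_max + R1 * (1 - exp(-b (eps - eps_el))) + R2 * (eps - eps_el)

   where R1 = S_sat - S_max (negative R1 = post-yield softening), R2 = 0,
   b = 10. Marrow-valued voxels receive a small stiffness floor so the whole
   VOI stays meshable.

3. **FE solve.** One cubic element per voxel (shared vertices, B-bar
   quadrature), bottom surface fixed, a displacement ramped uniformly over
   50 sub-steps to 0.1 % total strain on the top surface (axial for
   compression, lateral for x/y shear; orthogonal top motion restricted).
   Newton–Raphson equilibrates each sub-step with von Mises plasticity
   integrated by backward-Euler radial return. After each sub-step the mean
   top-surface von Mises stress is recorded; the Tb modulus is the slope of
   the linear section of that stress–strain curve.

4. **Analysis.** Tb/marrow stress partition (Welch t-test), 99th-percentile
   normalized stress maps, the BVF-weighted loaded-bone fraction
   `sum(tau * BVF) / sum(BVF)`, and two-scanner reproducibility reports
   (Pearson r and two-way ICC, absolute-agreement or consistency form).

Preprocessing utilities (threshold segmentation, bone-axis estimation,
single-pass Lanczos align-and-resample at 150 µm, periosteal peeling,
percent-site VOI selection) and a seeded plate/rod phantom generator with a
PSF + noise scanner simulator complete the pipeline.

## Worked example

```r
library(tbfe)

ph  <- generatePhantom(phantomSpec(gridSize = 24L, seed = 7L))  # BV/TV 0.424
ash <- chaToAsh(bmdToCha(ph$volume))       # BMD -> CHA -> ash density
res <- runProtocol(ash, keepStates = TRUE) # compression + x/y shear

res$compression$modulus
#> ModulusResult [compression]: 6476 MPa (window 1..50, r^2 = 1.000000)
res$y_shear$modulus
#> ModulusResult [y_shear]: 4286 MPa (window 1..50, r^2 = 1.000000)

vm <- res$compression$finalState@vonMises
partitionStats(vm, ph$mask)
#> StressPartition: Tb 18.2 +/- 2.18 MPa (n=5858) vs marrow 0.0799 +/- 0.0117 MPa (n=7966)
#>   Welch t = 637, p = 0

tau <- normalizeStress(elementsToGrid(res$mesh, vm))$tau
bvf <- bvfFromBmd(ph$volume)
loadedFraction(tau, bvf, bvf > 0.5)
#> [1] 0.89
```

The compressive modulus is the slope of the stress–strain curve over its
linear window (here the whole ramp: the phantom stays elastic at 0.1 %
strain). The partition confirms the continuum principle that stress
propagates through the trabecular network with nominal leakage into marrow,
and the loaded fraction summarizes how much of the bone phase carries it.

A thin command-line wrapper is provided in `inst/cli/tbfe.R`
(`tbfe.R run|phantom|repro ...`) for shell-driven use.

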