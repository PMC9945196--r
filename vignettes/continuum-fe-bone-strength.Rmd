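---
title: "Continuum voxel finite elements for trabecular bone strength: models, parameters and design choices"
author: "tbfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum voxel finite elements for trabecular bone strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbfe)
```

# The model

`tbfe` computes trabecular-bone (Tb) strength surrogates from calibrated CT
density volumes without segmenting bone from marrow. Its chain is:

1. CT numbers (HU) → BMD (g/cc) by an OLS calibration line from a
   density-phantom scan;
2. BMD → CHA density → ash density by fixed affine maps
   (`bmdToCha()`, `chaToAsh()`; constants `D_CHA` = 3.18 g/cc,
   `D_water` = 1 g/cc, ash = 0.0633 + 0.887 · CHA);
3. ash density → per-voxel elastoplastic parameters (`materialFromAsh()`);
4. a voxel-conforming hexahedral mesh and a displacement-controlled
   nonlinear solve per load mode (`runProtocol()`);
5. stress-partition, loaded-fraction and two-scanner reproducibility
   statistics.

The defining assumption of the continuum approach is that *every* voxel is
load-bearing material whose stiffness scales with its mineral content.
Partial-volume voxels — the majority of the trabecular compartment at
clinical CT resolution — contribute proportionally rather than being forced
to a bone/marrow decision. The cost is that "material" parameters at
marrow-valued densities are nominal (see floors below); the benefit is
robustness of the derived moduli to scanner resolution, which the
reproducibility machinery quantifies.

## Constitutive law

Each element follows isotropic small-strain elastoplasticity with a von
Mises yield surface and the mixed Swift–Voce isotropic hardening curve

$$S(\varepsilon) = S_{max} + R_1\!\left(1 - e^{-b(\varepsilon-\varepsilon_{el})}\right) + R_2(\varepsilon-\varepsilon_{el}), \qquad \varepsilon > \varepsilon_{el},$$

with $R_1 = S_{sat} - S_{max}$, $R_2 = 0$ and $b = 10$; below
$\varepsilon_{el}$ the response is linear with modulus $E$. A negative
$R_1$ (i.e. $S_{sat} < S_{max}$) gives post-yield softening; the solver is
validated on softening single elements, where the radial-return Newton
iteration remains convergent because $|dS/d\alpha| \ll 3G$.

Two points are deliberate design choices rather than given facts:

- **Yield strain.** $\varepsilon_{el} := S_{max}/E$, the strain where the
  elastic limb meets the plastic limb of the bilinear-to-plastic
  construction. An override (`materialLaw(epsEl = ...)`) exists for
  sensitivity studies.
- **Hardening argument.** The flow stress is evaluated at
  $\varepsilon_{el} + \alpha$, where $\alpha$ is the accumulated equivalent
  plastic strain. On a uniaxial strain ramp this reproduces the printed
  curve up to a shift of order $(\,\sigma-S_{max})/E \lesssim 10^{-3}$ in
  strain, which is below 0.5 % in stress for bone-like parameters; the
  single-element tests bound it explicitly.

## Density laws and their parameters

The density-to-parameter equations are deliberately configuration, not code
constants, with Keyak-family defaults (`materialLaw()`), because this is
where site- and study-specific calibration legitimately enters:

| parameter | default | units | meaning |
|---|---|---|---|
| `ECoef`, `EExp` | 14900, 1.86 | MPa | $E = 14900\,\rho_{ash}^{1.86}$ |
| `SmaxCoef`, `SmaxExp` | 102, 1.8 | MPa | $S_{max} = 102\,\rho_{ash}^{1.8}$ |
| `SsatRatio` | 0.9 | – | $S_{sat} = 0.9\,S_{max}$ (mild softening) |
| `EFloor` | 0.01 | MPa | marrow stiffness floor |
| `SmaxFloor` | 0.001 | MPa | marrow yield floor |
| `b` | 10 | – | Voce saturation rate |
| `R2` | 0 | MPa | Swift linear slope |
| `poisson` | 0.3 | – | Poisson ratio, all elements |

The floors keep the stiffness matrix positive definite on all-voxel meshes
while contributing negligibly to the load path; their ratio sets the floor
material's yield strain at 0.1, far beyond any strain it sees at the 0.1 %
protocol, so marrow never enters the plastic branch spuriously. Negative
CHA densities (fat-rich marrow darker than water) are *not* clipped during
densitometry — only the material map floors them — so calibration faults
stay visible in the density volumes.

# The solver

**Discretization.** One 8-node trilinear hexahedron per voxel, 2×2×2 Gauss
quadrature with mean-dilatation (B-bar) volumetric treatment by default.
B-bar avoids the volumetric locking that full integration exhibits at
ν = 0.3 with near-incompressible plastic flow; full integration is
selectable (`solverSettings(quadrature = "full")`) and is used where tests
compare against brute-force integration oracles.

**Loading.** The bottom node layer is fixed in all directions; every top
node receives the prescribed displacement component (axial for compression,
lateral for shear) ramped uniformly over `nSubsteps` (default 50) to
`totalStrain` (default 0.001), with orthogonal top-node motion restricted.
Shear cases change the displacement *direction*, never the loaded faces. A
"validation" BC mode releases the lateral constraints (with minimal
rigid-mode pins) so closed-form uniaxial states are admissible; it exists
for verification and is defined for compression only.

**Newton iteration and tolerances.** Each sub-step is equilibrated by
Newton–Raphson with the consistent algorithmic tangent of the radial-return
update. Convergence requires both L2 criteria: force residual ≤ 0.5 % of
the reaction-force norm and last displacement correction ≤ 5 % of the
sub-step increment (the conventional solver defaults for this tolerance
pair; the norm choice — L2 rather than max — and both tolerances are
configurable). A residual
three orders below the force tolerance terminates on its own, so purely
elastic sub-steps do not pay an extra factorization.

**Elastic fast path.** Under displacement control the pre-yield response is
exactly linear in the load factor. `solveLoadCase(method = "auto")` solves
the full-load elastic problem once, screens every element's trial von Mises
stress against its yield stress, and if none yields emits all sub-step
states by scaling. This is an exact shortcut, not an approximation, and is
cross-checked against the incremental Newton path in the tests. All three
production load cases constrain the same DOFs, so `runProtocol()` assembles
the elastic stiffness once and reuses it across modes.

**Linear solves.** Sparse Cholesky (CHOLMOD) up to 20 000 free DOFs,
Jacobi-preconditioned conjugate gradients (relative residual 10⁻⁸) beyond;
both produce identical solutions within solver tolerance and the choice is
configuration (`linearSolver`). The CG threshold reflects the memory
profile of fill-in for 3-D voxel meshes under AMD ordering. Semi-definite
systems from unanchored voxel components are caught *structurally*: before
solving, voxels without a 26-connected load path to the fixed bottom layer
raise an anchoring error (or are dropped with a warning when
`dropFloating = TRUE`), because such systems can be numerically consistent
and would otherwise silently yield rigid-motion solutions.

**Kinematics.** Small-strain throughout. At 0.1 % total strain geometric
nonlinearity contributes at O(10⁻³) relative, and the small-strain form
keeps the solver verifiable against closed forms; the
`geometricNonlinearity` flag is reserved.

# Modulus extraction

The modulus is the slope of the "linear section" of the curve of mean
top-surface von Mises stress versus applied strain. The published procedure
names no criterion for that section; `extractModulus()` operationalizes it
as the **longest initial sub-step window whose least-squares fit keeps
r² ≥ 0.9999**, slope of that fit, with a two-point-secant fallback (plus
warning) if no window qualifies. The threshold is strict because solver
curves are noise-free: at 0.999 a bilinear curve with a sharp yield kink
admits one post-kink point into the window; 0.9999 excludes it while still
accepting every genuinely elastic ramp (r² = 1 to machine precision).
Stress averaging over the top surface uses element-centroid values; for the
symmetric quadrature rule the centroid evaluation coincides with the
Gauss-point mean in the elastic case.

The shear "modulus" follows the same construction — top-surface von Mises
slope against applied lateral strain — and is *not* the engineering shear
modulus: a pure shear stress τ carries von Mises weight √3 τ, so values are
inflated accordingly and should only be compared within-method.

# The phantom generator and scanner simulator

`generatePhantom()` builds periodic parallel plates (normal to a chosen
axis, planes containing the loading axis) with optional bridging rods on a
seeded random phase, in BMD units so the entire calibration chain is
exercised. Defaults place plate thickness (250 µm) and period (650 µm) in
the physiologic distal-tibia range, and the cohort generator draws
thickness 200–320 µm and period 550–750 µm per subject — the physiologic
scales at that site — plus mineralization 1.0–1.35 g/cc CHA and rod
fraction 0.05–0.3.

`simulateScanner()` applies an isotropic Gaussian PSF, resamples to the
reconstruction grid, and adds seeded Gaussian noise. The default scanner
pair (350 vs 250 µm FWHM, equal noise 0.01 g/cc, equal 150 µm output grid)
models two ultra-sharp bone kernels of modestly different resolution, i.e.
a scanner upgrade rather than a modality change.

**What the phantom does *not* emulate:** anatomically curved trabeculae and
cortices, spatially varying marrow composition, beam hardening and scatter,
projection-domain noise correlation, and scanner-specific kernel shapes.
Passing tests therefore demonstrate correctness of the computational chain
and the *direction* of resolution effects (partial-volume thickening,
modulus reproducibility), not clinical effect sizes. Cohort-level numbers
printed by `scripts/acceptance.R` are properties of this synthetic study.

# Preprocessing

- **Segmentation** is a documented stand-in (threshold, largest
  26-connected component, cavity fill); validated anatomical segmentation
  algorithms are out of scope.
- **Bone axis**: per-slice centroids of the peeled mask, line fit over the
  region proximal to the configured percent site. A raw principal axis of
  the voxel cloud is biased by the slant-cut end faces of a tilted shaft
  (about 1.4° at test geometry); the centroid line is exact for shaft-like
  masks, and the sign is fixed to +z.
- **Alignment/resampling** composes the rotation-to-axis and the
  resampling to 150 µm into a single windowed-sinc interpolation pass
  (Lanczos, default a = 5, configurable — the specific window is this
  package's choice). Weights are renormalized to unit sum, and a test
  verifies one combined pass beats two sequential ones in RMS on a
  band-limited pattern.
- **Peeling** is iterative 2-D erosion (3×3 cross) per axial slice until
  the target area reduction is met — the first mask at or below target is
  kept, which lands within one erosion step (≈ 1 voxel of radius) of the
  continuum value. **Percent sites** are measured from the most distal
  mask slice, with the tibial length supplied by configuration (synthetic
  phantoms provide it exactly; full-bone scans are out of scope).

# Statistics

`icc()` computes single-measurement ICCs from the two-way ANOVA mean
squares. The default form is **ICC(A,1)** — two-way mixed effects, absolute
agreement — because the two scanners are fixed conditions and absolute
agreement is the stricter cross-scanner claim; the consistency form
ICC(C,1) is selectable and reported alongside its identifier. The forms
differ exactly by the between-column variance term, so a constant
between-scanner offset degrades A1 but leaves C1 at 1 (tested). Percentile
capping for normalized stress maps uses the linear-interpolation (type-7)
rule, fixed and documented because τ maps depend on it; the cap is computed
over the whole VOI by default (bone-only capping is a one-argument change).
Welch's unpaired t-test partitions Tb vs marrow stresses; paired t-tests
compare loaded fractions across load modes.

# Degenerate inputs and tie-breaks

- Meshes one element layer thick along the loading axis are rejected as a
  boundary error (no valid platen pair).
- Calibration requires ≥ 2 distinct HU samples; all-identical rating tables
  make the ICC undefined (flagged NA with a warning).
- All-zero stress fields refuse normalization; zero BVF mass refuses the
  loaded fraction.
- Node numbering, assembly order and the RNG funnel (one seed per phantom /
  cohort / scanner draw) are deterministic, so identical inputs give
  bit-identical meshes and reproducible cohorts.

# Problem sizes

The test suite verifies the solver on closed forms (8³ homogeneous cube,
two-layer 6×6×16 column, 2×2×2 patch test), against dense brute-force
oracles at 3×3×3 with plasticity active, and runs the study-level
properties on a 48³ phantom (stress partition) and a 10-subject 32³
two-scanner cohort (reproducibility ordering). `scripts/acceptance.R` uses
the same 10-subject 32³ cohort. These sizes were chosen to exercise the
sparse/CG code paths at realistic VOI scale while keeping a full run in the
minutes range on a single core; the method itself has no size-specific
constants.

# Known limitations

- Isotropic material per voxel; no fabric-based anisotropy, strain-rate
  dependence, damage accumulation or failure-load search.
- Small-strain kinematics (see above); contact with platens is idealized
  as displacement control.
- The shear modulus is the method's own construction (von Mises-based) and
  is not comparable to classical shear moduli.
- The Tb/marrow mask for partition statistics is a BVF threshold (0.5
  default), a stand-in for dedicated segmentation algorithms; partition
  *statistics* are robust to the exact mask, but voxel counts are not.
- MetaImage I/O covers uncompressed files only; NIfTI I/O assumes
  isotropic spacing recorded in millimetres.
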