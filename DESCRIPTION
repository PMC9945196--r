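Package: tbfe
Title: Nonlinear Continuum Finite-Element Analysis of Trabecular Bone Strength from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes trabecular bone microstructural strength (compressive and
    shear moduli) directly from calibrated CT density volumes using a nonlinear
    continuum voxel finite-element method with an elastoplastic Swift-Voce
    hardening law, without requiring binary bone/marrow segmentation. Includes
    QCT phantom-based density calibration (HU to BMD to CHA to ash density),
    voxel hexahedral meshing, a displacement-controlled Newton-Raphson solver
    with von Mises plasticity and radial-return integration, stress-partition
    and loaded-bone-fraction analyses, preprocessing (bone-axis alignment,
    windowed-sinc resampling, periosteal peeling, percent-site VOI selection),
    a parametric plate/rod trabecular phantom generator with a two-scanner
    imaging simulator, and multi-scanner reproducibility statistics (Pearson
    correlation and intraclass correlation coefficients).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
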