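Package: aortaflow
Title: Aortic Hemodynamics from 4D Flow Cardiovascular MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved three-directional
    phase-contrast (4D flow) cardiovascular MRI of the thoracic aorta:
    eddy-current background-phase correction, velocity anti-aliasing,
    PC-MRA computation and peak-systole detection; centerline extraction,
    nine-plane quantification geometry, wall meshing and an 18-region wall
    atlas; per-plane flow volumes, systolic 3D wall shear stress,
    peak-velocity maximum-intensity projections and semi-quantitative
    helix/vortex grading from pathlines; and nonparametric cohort
    statistics with exact small-sample p-values. A digital aorta phantom
    generator with analytic ground truth (Poiseuille flow in straight and
    U-shaped tubes, injectable aliasing wraps, background phase offsets
    and noise) supports validation in place of protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
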