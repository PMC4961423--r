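Package: fetlockfe
Title: Voxel-Based Finite-Element Analysis of Impact Loading in the
    Equine Fetlock Joint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Subject-specific finite-element modelling of the distal third
    metacarpal (MC3) condyle under primary-impact and midstance loading.
    Generates synthetic CT-like condyle phantoms (healthy and
    osteoarthritic variants), maps CT density to bone elastic modulus via
    a power-law calibration (E = 9040 rho^2.35), builds voxel hexahedral
    or tetrahedral meshes with anatomical region labels, solves the static
    midstance case and the explicit-dynamic impact of MC3 against the
    proximal phalanx with penalty contact and Coulomb friction, and
    post-processes regional von Mises stress and contact pressure on
    160-point sampling grids, including mesh-convergence and
    stiffness-sensitivity harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
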