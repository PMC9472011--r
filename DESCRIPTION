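Package: woundpath
Title: Planning and Tracking Computations for Adaptive In Situ Bioprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline of an adaptive multi-degree-of-freedom in
    situ bioprinting robot for skin-wound repair: wound segmentation and
    binocular 3D localization, eye-in-hand hand-eye calibration, six-axis
    Denavit-Hartenberg kinematics with Monte Carlo workspace and kinematic
    error maps, wound-surface reconstruction with defect-volume computation,
    conformal six-coordinate toolpath generation with volume-exact bioink
    allocation, and a closed-loop visual tracking simulator. Includes
    deterministic synthetic-fixture generators (dot grids, stereo wound
    renders, crater meshes, hand-eye pose sets) so every stage is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    rlang,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    Matrix,
    withr,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
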