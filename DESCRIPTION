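Package: adaptrt
Title: Robustness Settings and Plan-Adaptation Trade-Offs in Scanned Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for quantifying the trade-off between
    robust-optimization margins and plan-adaptation frequency in
    intensity-modulated proton therapy of head-and-neck cancer. Generates
    synthetic voxelized neck phantoms with progressive weekly anatomical
    change, computes scanned-proton dose with a simplified analytic
    pencil-beam engine, builds reference and margin-reduced plans by
    composite minimax robust optimization and dose-mimicking
    re-optimization, evaluates plans on weekly anatomy snapshots with
    voxel-wise minimum/maximum scenario dosimetry and D98/D2 coverage
    criteria, accumulates dose over the treatment course, and summarizes
    adaptation-trigger failure rates with Wilson intervals, two-proportion
    z-tests, Holm correction, TOST equivalence tests, logistic NTCP
    models, and ordinary-least-squares trade-off slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
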