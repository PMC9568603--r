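Package: beadcycle
Title: Trajectory Inference for Optically Trapped Bacteria-on-a-Bead Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for bacteria-on-a-bead
    experiments, in which predivisional Caulobacter crescentus cells attached
    to colloidal beads are observed free-swimming or held in an optical trap.
    Provides a ground-truth-labeled synthetic data generator (overdamped
    Langevin dynamics of a trapped bead driven by flagellar gyration, type IV
    pilus attachment cycles and long-axis rotation; run-reverse free swimmers;
    rotating-pole tracks of surface-attached cells; rendered image stacks),
    sub-pixel bead tracking, trap-stiffness calibration (equipartition and
    power-spectral-density methods), flagellar force inference, behavioral
    state segmentation with pilus-cycle extraction, and swim/rotation
    statistics, so that every printed summary quantity of the assay can be
    verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
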