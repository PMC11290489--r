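Package: RAMPscreen
Title: Multiplexed Suspension Bead Array Mapping of GPCR-RAMP Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed suspension bead array (SBA)
    screens of G protein-coupled receptor (GPCR) and receptor
    activity-modifying protein (RAMP) complex formation. Implements
    normalization and quality control of median fluorescence intensities
    (signal-to-noise ratios, quantile normalization, Z and robust Z scores),
    literature-calibrated sensitivity-specificity threshold selection for
    epitope-based capture-detection schemes, kernel-density plus MAD
    thresholds for protein-based capture antibodies, evidence-class voting
    across schemes, integration into yes/no/inconclusive interactome
    annotations, and downstream expression-ratio, transducer-coupling and
    in situ proximity (RCP) statistics. A seeded synthetic-screen generator
    with known ground truth makes every stage testable without access to
    raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    limma,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, Normalization, QualityControl, Software
RoxygenNote: 7.3.3
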