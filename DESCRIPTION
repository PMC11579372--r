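Package: tdcsfield
Title: Finite-Element tDCS Field Modelling, Tissue-Thickness Geometry, and
    Mediation Analysis on Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates transcranial direct current stimulation (tDCS) electric
    fields on labeled tetrahedral head models with a first-order finite element
    solver for the quasi-static potential problem, including sponge-electrode
    montages, current normalization, and region-of-interest field extraction.
    Provides a normal-vector tissue-thickness algorithm (scalp, skull, CSF,
    cortex, and their scalp-to-cortex aggregate), layered-sphere head phantom
    generation with BMI-linked scalp thickness, synthetic cohort simulation,
    covariate-adjusted group statistics with Cohen's f2 and sensitivity
    analysis, and causal mediation analysis (ACME/ADE/total effects) with
    nonparametric bootstrap intervals. Includes analytic validation oracles
    (slab and multi-shell sphere series) and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
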