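Package: lc8screen
Title: Screening LC8 Binding Sites with Structure-Prediction Confidence Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting LC8 (dynein light chain, DYNLL1)
    binding sites in intrinsically disordered client proteins from the
    confidence scores of AlphaFold-Multimer/ColabFold structure predictions.
    Parses client proteins into overlapping windows and writes multi-chain
    FASTA inputs, reads ColabFold-style prediction directories (score JSON
    plus PDB coordinates), extracts five interface scores per structure
    (model confidence, binding-interface pLDDT, directional PAE between the
    LC8 beta3 strand and the bound client in both directions, and the LC8
    dimer-interface PAE), links one-client and two-client runs into
    ten-parameter score vectors, classifies binders with composite threshold
    sets (shipped exclusive and inclusive defaults, retrainable by a genetic
    algorithm maximizing Pareto-frontier AUROC), correlates scores with
    measured binding affinities (least-squares fits, multiplicity-corrected
    p values, adjusted mutual information over binning strategies), predicts
    rough dissociation constants for new sites with anchor-class specific
    linear models, and aggregates qualitative Bayesian evidence as additive
    decibel log-odds. A synthetic-fixture generator emulates prediction
    output for testing and calibration without running AlphaFold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    Biostrings,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
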