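Package: photoxl
Title: Quantitative Analysis of Alkyl-Diazirine Photo-Cross-Linking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative dissection of alkyl-diazirine
    photochemistry in photo-cross-linking (PXL) mass spectrometry.
    Provides closed-form photolysis kinetics for four candidate reaction
    schemes with model discrimination from multiple-reaction-monitoring
    (MRM) time courses, estimation of composite photolysis rates and the
    diazo/carbene branching ratio, a five-channel competition-kinetics
    model of residue reactivity with diazo-versus-carbene mechanism
    classification and irradiation-condition optimization, cross-link to
    structure distance mapping (C-alpha distances, maximally allowed
    distances, over-length flagging, residue-type enrichment, solvent
    accessibility), and seed-deterministic synthetic-data generators that
    emulate the instrument outputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
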