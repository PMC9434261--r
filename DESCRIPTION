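Package: muropep
Title: Muropeptide Precursor Identification and Mur Ligase Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting UDP-linked peptidoglycan (murein) precursors
    in negative-ion nanospray TOF peak lists and for characterising the Mur
    ligases that build them. Provides a compositional algebra for
    nucleotide-linked muropeptides (building blocks, condensation assembly,
    monoisotopic masses), enumeration of deprotonated and sodium-exchanged
    ion species, ppm-tolerance peak matching with per-intermediate
    identification reports, enzyme kinetics for the coupled NADH/ADP-release
    assay (initial rates, Michaelis-Menten and substrate-inhibition fits
    with model comparison, diprotic pH-rate profiles, amino-acid specificity
    statistics), light-weight sequence utilities (DAP-specificity motif
    scanning, transit-peptide trimming, pairwise identity), and seeded
    synthetic-data generators that emulate the instrument and the plate
    reader so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
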