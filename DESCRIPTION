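Package: dastm
Title: Dense Alignment Surface Prediction of Transmembrane Helices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts alpha-helical transmembrane (TM) segments from a
    protein's amino acid sequence alone using the dense alignment surface
    (DAS) approach: gapless pairwise comparison of the query against a
    small library of reference TM proteins under a hydrophobicity-derived
    scoring matrix, projection of each alignment surface onto the query
    axis as a cross-weighted cumulative score profile, and averaging over
    the library into a global DAS profile that is thresholded at 2.5 to
    call TM segments.  Includes signal-peptide and twin-peak warnings, a
    TM/non-TM protein classifier, a per-segment benchmark protocol based
    on a minimum-overlap matching rule with signal-peptide exclusion,
    seeded generators for synthetic TM, globular and signal-peptide
    proteins, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    seqinr,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
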