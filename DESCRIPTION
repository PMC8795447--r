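Package: grkselect
Title: GRK-Selective Beta-Arrestin Recruitment Analysis from BRET Plate Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduces dual-channel (donor/acceptor) BRET plate-reader time
    series to mock-, baseline- and vehicle-corrected "delta net BRET fold
    changes", gates conditions for functional beta-arrestin recruitment, fits
    gated concentration-response curves (three- or four-parameter logistic),
    classifies GPCR-arrestin pairs by GRK selectivity from Bonferroni-adjusted
    comparison matrices with Canberra-distance clustering, detects
    ligand-independent receptor-arrestin pre-coupling from elevated baseline
    ratios (one-sided Dunnett), scans receptor intracellular segments (IL3 and
    C-terminus) for Ser/Thr phospho-sites and P/X phospho-motif grammars with
    positional Fisher-exact association tests, and analyses label-free dynamic
    mass redistribution traces by area under the curve. A seeded synthetic-data
    generator with known ground truth makes every stage testable without raw
    plate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    minpack.lm,
    mvtnorm,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
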