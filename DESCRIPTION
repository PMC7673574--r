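Package: pteridosurvey
Title: Barcode-Gap, Richness, and Monophyly Analysis for Floristic Molecular Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-marker (e.g. plastid rbcL) molecular
    surveys of a flora. Computes raw (uncorrected) pairwise distances with
    pairwise deletion from an aligned reference library, per-taxon minimum
    interspecific distances and barcode failure rates, cross-flora comparisons,
    incidence-based species-richness rarefaction/extrapolation with Chao2
    asymptotic estimates and bootstrap confidence intervals, a neighbor-joining
    monophyly screen, and floristic checklist summary statistics. Includes a
    synthetic-flora generator so every stage runs at desk scale without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    phytools,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Collate: 
    'utils.R'
    'core_io.R'
    'distances.R'
    'barcode_gap.R'
    'phylo_screen.R'
    'richness.R'
    'plots.R'
    'pteridosurvey-package.R'
    'synthetic_data.R'
    'reporting.R'
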