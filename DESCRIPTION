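Package: synscreen
Title: Synapse Proteome Enrichment and Extracellular Interactome Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for synapse type-specific proteomics and
    cell-surface interactome screening. Implements label-free spectral-count
    enrichment analysis (peptide filtering, NSAF normalization,
    zero-imputation, per-protein t tests, Benjamini-Hochberg q-values with a
    5 percent FDR cutoff), an ELISA plate-screen caller (blank-well background
    estimation, fold-over-background thresholding, promiscuous-prey rejection,
    cross-experiment merging, interaction-network assembly), ecto-Fc pull-down
    spectral-count hit filters, and one-site steady-state biolayer
    interferometry affinity fitting. Seeded synthetic-data generators emulate
    each input so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
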