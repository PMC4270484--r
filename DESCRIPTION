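Package: orthopeaks
Title: Cross-Species Conservation of Transcription-Factor Occupancy and
    Chromatin-Based Models of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-epigenomics toolkit for ChIP-seq studies spanning
    two species. Reimplements chain-file (liftOver-style) interval mapping
    with unique-hit and minimum-match semantics, classifies
    transcription-factor occupancy sites into conserved, lost,
    compensatory, gained and strongly-gained categories, clusters summits
    into combinatorial co-occupancy regions and measures their
    cross-species transfer, runs permutation-based genomic association and
    chromatin-state overlap enrichment, quantifies promoter signal from
    tag files, and fits L1-penalized (lasso) consensus models that predict
    gene expression - and between-species expression differences - from
    promoter epigenomic marks. A synthetic paired-genome generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
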