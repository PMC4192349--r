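Package: hetrseq
Title: ChIP-Seq Peak Calling, Curation and Binding-Site Discovery for the
    HetR Regulon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible bacterial ChIP-seq analysis workflow for
    mapping transcription-factor binding sites, developed around the
    heterocyst master regulator HetR of filamentous cyanobacteria.
    Provides windowed Poisson enrichment peak calling against a
    non-enriched control with Benjamini-Hochberg false discovery rate
    control, technical-replicate splitting with 2-of-3 consensus
    retention, biological peak curation (fold enrichment, strand-offset
    twin-peak morphology, gene-proximity categories, mutant-misregulation
    cross-referencing), FiMO-style position weight matrix scanning with
    exact score p-values, consensus motif construction with information
    content and IUPAC calls, and genome-relative functional-category fold
    enrichment. A synthetic-data generator emulates the sequencing design
    (bacterial-scale genome, planted motif instances, sonication
    twin-peak read geometry, wild-type versus mutant expression tables)
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
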