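Package: riphewas
Title: Phenome-Wide Association Scanning for Recombinant-Inbred Panels
    and Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("BXD", "Phenomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for joint mouse-human phenome-wide
    association (PheWAS) analysis. Implements variant consequence
    annotation against transcript models, composite impact scoring of
    noncoding SNPs from regulatory-element and conservation tracks,
    event-wise read-depth copy-number variant detection in 100 bp
    windows, correlation-based PheWAS scanning of recombinant-inbred
    strain panels with Storey q-value FDR control, and a phecode-style
    clinical PheWAS stage with additive logistic regression. Ships a
    synthetic-data module that emulates a two-parent recombinant-inbred
    panel, multiscalar phenomes with planted marker effects, gene models
    with planted variants, depth tracks with planted copy-number events,
    and an ICD-coded cohort, so every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    data.table,
    jsonlite,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
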