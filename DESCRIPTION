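Package: shmselect
Title: Antigen-Selection Analysis of Somatic Hypermutation in
    Immunoglobulin Heavy-Chain Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing somatic hypermutation in rearranged
    immunoglobulin heavy-chain (IGHV) sequences from amplicon repertoire
    sequencing. Provides germline reference handling with framework/CDR
    region maps under Kabat, IMGT and broadened (union) definitions,
    V(D)J annotation by local alignment, isotype assignment from
    constant-region primer sites, orientation-aware read deduplication,
    a three-stage quality and clonality filter cascade,
    replacement/silent mutation classification, and a binomial
    random-mutation model that classifies each sequence as showing or
    lacking evidence of antigen selection, with group-level comparisons
    between isotypes. A synthetic-repertoire generator with a full truth
    table emulates 454-style pyrosequencing reads (clonal replicate
    amplicons, bidirectional reads, 5' primer truncation, homopolymer
    indels) so that every pipeline stage can be exercised and calibrated
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
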