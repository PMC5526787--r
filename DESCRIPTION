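Package: croatan
Title: Design and Analysis of Single and Dual-sgRNA CRISPR Knockout Reagents
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores candidate Cas9 targets by combining a stringency ladder of
    cost-weighted random forests trained on sgRNA efficacy data, a
    microhomology-based model of double-strand-break repair that estimates
    frameshift likelihood, and cut-site amino-acid conservation, consolidating
    the three into a 1-9 guide score. Pairs guides into dual-promoter
    constructs by heuristic pair scoring followed by exact maximum weight
    matching, analyses pooled knockout screens (read-count filtering, log
    fold changes, gene-level hit calling with true/false positive rates), and
    classifies dual-cut genomic scars from aligned amplicon reads. Includes
    seed-deterministic simulators for every input so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
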