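Package: nanotriage
Title: Variant Triage, Structural-Variant Prioritization and Run QC for
    Rapid Nanopore Sequencing Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analytic toolkit for ultra-rapid long-read diagnostic
    sequencing: homopolymer-aware annotation of small variants, a score-based
    rapid variant prioritization tree alongside the conventional any-criterion
    trigger tree, rare structural-variant selection against population
    catalogs with three-tier prioritization and benchmark evaluation
    (precision/recall/F1 and exact breakpoint matching), windowed read-depth
    summaries with aneuploidy flagging, barcode carryover-rate estimation
    with in-silico contamination mixing, and longest-processing-time
    scheduling of per-contig variant-calling workloads. Deterministic
    synthetic-data generators with ground-truth manifests make every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
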