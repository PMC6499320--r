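Package: svmosaic
Title: Multi-Caller Structural Variant Merging, Cross-Sample Clustering and
    Benchmarking for Plant Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building population-scale structural variant (SV)
    catalogs from short-read resequencing panels. Implements within-sample
    integration of call sets from multiple SV callers with anchor-caller and
    two-caller-support retention rules, cross-sample clustering of calls into
    allelic events via reciprocal-overlap similarity graphs and
    complete-linkage agglomeration, a simulation-based benchmark evaluator
    with reciprocal-overlap and breakpoint-error matching criteria over SV
    size bins, and downstream genome annotation and regulatory statistics:
    transposable-element overlap classification, TSS-relative SV profiles,
    transcription factor binding site independence testing, linguistic
    sequence complexity, SV density windows, fully deleted genes, and gene
    set enrichment. A seeded synthetic-data module generates genomes, truth
    SV sets, emulated caller outputs and annotation tracks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
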