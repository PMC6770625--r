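Package: retrospect
Title: Ranking Regulatory Evolution of Genes and Pathways from
    Retroelement-Linked Histone Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores genes and molecular pathways by the proportion of
    histone-modification ChIP-seq tags linked to retroelements (SINE, LINE,
    LTR/ERV) within the 10 kb neighborhood of each transcription start site.
    Implements per-gene RE-linked enrichment scores (GRE, GHE, NGRE), their
    pathway-level aggregates (PII, PGI, NPII), averaging across cell lines,
    outlier calling of RRE-enriched and RRE-deficient genes and pathways via
    one-parameter regression through the origin, EASE (conservative
    hypergeometric) category enrichment with Fisher's-method aggregation,
    pairwise profile correlation with hierarchical biclustering, and a fully
    synthetic annotation/tag generator with planted signal so the whole
    pipeline can be exercised and validated without external genomics
    resources.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
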