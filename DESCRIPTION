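Package: locuspacket
Title: Standardized Per-Locus Evidence Packets for GWAS Candidate Gene
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles standardized per-locus evidence "packets" to support
    candidate gene prioritization from broad GWAS intervals, particularly in
    model-organism genetic reference populations where loci span megabases and
    contain dozens to hundreds of genes. Takes QTL intervals or gene lists,
    harmonizes gene identifiers, attaches arbitrary study-specific evidence
    tables (differential expression, cis-eQTL calls, coding variants) as
    namespaced per-gene layers joined by symbol, Ensembl ID, or genomic
    overlap, merges in gene-trait annotations mined from InterMine-style and
    Open Targets-style services (offline-first, with a content-addressed
    request cache), screens genes with a safe boolean criteria mini-language
    distinguishing required from supportive evidence, and emits identically
    structured comparison sheets, UpSet evidence-overlap summaries, and
    locus-zoom figures with haplotype-effect tracks. Includes a deterministic
    synthetic-data generator with a planted-truth manifest so end-to-end
    pipeline counts are exactly checkable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    patchwork,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    httr,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
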