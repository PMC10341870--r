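Package: txwaves
Title: Transcriptional Wave Analysis for Stimulus-Response RNA-seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of short bulk RNA-seq time courses of stimulated cells
    (e.g., purinergic and endotoxin activation of primary microglia).
    Implements trimmed-mean-of-M-values (TMM) normalization from its
    published definition, a conditioned negative-binomial exact test for
    two-group differential expression with Benjamini-Hochberg FDR, and a
    nine-class combined-trend classifier (Up/Same/Down at an early and a
    late timepoint) that separates transient from sustained transcriptional
    waves. Also provides gene-set expression-share profiling, coding versus
    non-coding biotype partitioning from GENCODE-dialect GTF annotation,
    PCA summaries, and a negative-binomial count simulator that plants
    known trend classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
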