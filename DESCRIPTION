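Package: nbscreen
Title: Multi-Criteria Driver-Gene Screens for Neuroblastoma Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements two multi-criteria gene-prioritization screens used
    to nominate candidate driver genes in neuroblastoma: a cohort-level
    five-criterion screen over a recurrently gained chromosome-17q region
    (copy-number binning and ploidy classification, negative-binomial
    differential expression with a data-dependent log2 fold-change
    threshold, expression/copy-number and expression/MYCN Pearson
    correlation filters, and a median-dichotomized survival filter), and a
    ChIP-seq five-criterion coactivator-target screen (promoter
    co-occupancy of MYCN, RNA polymerase II, H3K27ac and H3K4me3 together
    with ALYREF binding, a fold-enrichment cut-off and ranking, E-box motif
    scanning, and reuse of the survival and correlation filters plus a
    gene-set criterion).  A synthetic-cohort generator with planted ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    survival,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
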