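Package: ecdreg
Title: Ecdysone-Responsive Regulatory Element Mapping from Histone-Mark ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers hormone-responsive regulatory elements in the silkworm from
    histone-modification ChIP-seq: promoter and distal regulatory element (DRE)
    calling from H3K4me3/H3K4me1 peaks, activity classification by H3K27ac
    overlap, two-condition twofold-change dynamics of histone signal, nearest-
    gene expression linkage and TSS metaprofiles, and position-weight-matrix
    scanning for ecdysone response elements (EcREs) in receptor-binding peaks.
    Ships a ground-truth synthetic-data generator that emulates the statistical
    structure of a 20-hydroxyecdysone ChIP-seq experiment so every stage has a
    download-free recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
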