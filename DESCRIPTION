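Package: cisray
Title: Promoter k-mer Enrichment and DNase I Footprint Analysis for
    Auxin-Responsive Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of candidate cis-regulatory elements in promoters of
    hormone-responsive genes. Classifies genes as upregulated or
    non-responsive from per-gene expression statistics, extracts
    TSS-anchored promoter windows (-900..+100 by default) from a genome and
    its annotation, scores presence of reverse-complement-collapsed k-mer
    classes in each promoter, and tests each class for over-representation
    in a gene group against the all-gene background with the hypergeometric
    test. Also implements trimmed log2-ratio normalization of DNase I
    footprinting electropherogram peak tables with zero-sum per-sample
    factors, and lost/gained protection calling. Ships a synthetic-data
    generator (genome + GFF3, expression statistics, replicate peak tables)
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
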