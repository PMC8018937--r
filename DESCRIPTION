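Package: spliceq
Title: Cassette-Exon Junction Quantification for Tau 3R/4R Isoform Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cassette-exon splicing from spliced RNA-seq alignments
    by counting junction-spanning reads at defined exon-exon junctions and
    forming the 4R/3R-style usage percentage used to assay MAPT tau isoform
    composition. Includes per-gene models with cassette events (packaged
    porcine and human MAPT fixtures), depth normalization of junction counts,
    TPM and log2(TPM+1) expression profiling, DEXSeq-count style flattened
    exon-bin counting with relative exon usage, standard-curve RT-qPCR
    relative quantification normalized to the geometric mean of reference
    genes, and a seeded spliced-read simulator with ground-truth ledgers for
    end-to-end validation of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
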