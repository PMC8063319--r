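Package: poolscan
Title: Pool-Seq Divergence Scans with Calibrated Local-Score Outlier Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based divergence scans for pooled whole-genome sequencing
    (pool-seq) data: sync-format ingestion and SNP filtering, Weir-Cockerham
    and Karlsson window FST, nucleotide diversity (pi) and absolute divergence
    (dxy) by FST bin, Lewontin-Krakauer (LK) and kinship-corrected (FLK)
    single-SNP tests, and a Lindley-process local score with Monte-Carlo
    chromosome-wide significance thresholds.  A forward Wright-Fisher
    simulator with recombination and pool-read sampling provides strictly
    neutral pseudo-genomes for estimating the false-positive rate of the
    local-score scan, and an exact hypergeometric module tests gene-set
    enrichment of genes in highly differentiated windows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
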