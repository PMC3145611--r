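Package: peakatlas
Title: Composable ChIP-Seq Peak Interpretation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for interpreting ChIP-seq experiments in which
    every analysis step consumes and emits plain peak lists. Provides a
    read-density peak caller, interval-tree comparison of peak sets with
    randomization-based overlap significance, gene-level peak annotation
    (promoter, exon, first intron, intron, downstream, distal), hypergeometric
    pathway association, position-weight-matrix and regular-expression motif
    scanning with matched background-sequence generators, conservation
    filtering and binned profiles, read-density and read-count matrices with
    RPKM normalization, self-organizing-map and k-means clustering of density
    profiles, and a deterministic synthetic-fixture generator so the whole
    workflow can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
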