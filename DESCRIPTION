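Package: yeastmarks
Title: Histone-Modification and Chromatin-Regulator Enrichment Analysis for
    Yeast Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies histone modifications enriched or depleted in the
    promoters and coding regions of a user-supplied yeast gene list, and
    histone/chromatin regulators enriched in its promoters. Gene sets are
    built by thresholding the maximal ChIP signal over strand-aware promoter
    (500 bp upstream to 100 bp downstream of the start codon) and coding
    (start codon to stop codon) regions; over- and under-representation are
    tested with dual-tail hypergeometric p-values computed in log space, with
    Bonferroni or Benjamini-Hochberg correction. Includes readers for GFF3,
    bedGraph, wiggle and GMT inputs, a synthetic-study generator with planted
    enrichment for validation, report writers, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
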