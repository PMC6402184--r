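Package: lincnet
Title: Integrated lncRNA-miRNA-mRNA Expression and ceRNA Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline that turns lncRNA, miRNA and mRNA count
    matrices and transcript sequences into differential-expression calls
    (Audic-Claverie count test on pooled sequencing libraries, RPKM fold
    changes, Benjamini-Hochberg q-values), novel long-noncoding-RNA
    candidates (five-step filter cascade with an ORF scan and a hexamer
    coding-potential score), a lincRNA-mRNA Pearson coexpression network,
    cis (10-kb window) and trans (base-pairing) target predictions, a
    consensus-voted ceRNA (lncRNA-miRNA-mRNA) triad network, and
    hypergeometric gene-set enrichment.  A synthetic-data generator with a
    planted-truth manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
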