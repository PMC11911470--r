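Package: herbscreen
Title: Prioritization of Natural Products and Herbal Ingredients from
    GWAS and QTL Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks genes by disease association using summary-data-based
    Mendelian randomization (SMR) over pairs of QTL (eQTL/pQTL) exposure
    and GWAS outcome summary statistics, then prioritizes natural
    products and herbal ingredients by two-level preranked gene-set
    enrichment analysis with meta-analytic (Stouffer) consensus across
    dataset pairs. Includes instrument selection with FDR filtering, LD
    clumping, allele harmonization with palindrome handling, proxy SNP
    lookup, a permutation-based weighted Kolmogorov-Smirnov enrichment
    test with adaptive precision, multiple-testing adjustment, a seeded
    synthetic benchmark generator with planted ground truth, and a
    configuration-driven end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
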