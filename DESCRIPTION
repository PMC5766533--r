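Package: conjfdr
Title: Conditional and Conjunction False Discovery Rate Analysis of Paired GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-trait genetic-epidemiology workflow for pairs of genome-wide
    association study (GWAS) summary-statistics sets: harmonization to a common
    reference SNP panel, genomic control, decorrelation of test statistics for
    shared control samples, stratified quantile-quantile enrichment with
    LD-score-based fold-enrichment tests, empirical conditional and conjunction
    tail-area false discovery rates with random LD pruning, and greedy clumping
    of discoveries into independent loci. Includes a block-LD synthetic GWAS
    generator with ground truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
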