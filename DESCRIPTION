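Package: awmnet
Title: Multi-Trait GWAS Co-Association Networks via the Association Weight Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns multi-trait genome-wide association results into an annotated
    gene co-association network. Implements marker and sample quality control,
    a VanRaden genomic relationship matrix, EMMAX-style mixed-model association
    scans with pseudo-heritability estimation, construction of an Association
    Weight Matrix keyed on a focal phenotype, PCIT partial-correlation edge
    significance testing, MCODE density-based graph clustering, SNP-to-gene
    interval annotation, and hypergeometric term enrichment with Cohen's kappa
    functional grouping. Includes a synthetic half-sib population generator with
    planted pleiotropic QTL so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    ggplot2,
    generics,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
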