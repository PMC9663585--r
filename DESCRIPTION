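Package: pleioscan
Title: Cross-Trait Pleiotropy Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting pleiotropic loci shared by two
    complex traits from genome-wide association study (GWAS) summary statistics.
    Implements quality control and allele harmonization of per-SNP association
    tables, linkage-disequilibrium (LD) based SNP pruning against a reference
    genotype panel, a simplified LD score regression for SNP heritability and
    cross-trait genetic correlation with block-jackknife standard errors,
    empirical conditional and conjunction false discovery rates (cFDR/ccFDR),
    a four-group Uniform/Beta mixture model of paired p-values fitted by
    expectation-maximization with a likelihood-ratio test for pleiotropic
    enrichment, stratified Q-Q and fold-enrichment diagnostics, and seeded
    synthetic-data generators with known ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
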