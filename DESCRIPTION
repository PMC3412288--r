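Package: genefscan
Title: Gene-Based SNP-Set Association via LASSO Selection and Partial F-Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centric association testing of quantitative (typically
    imaging-derived) phenotypes. Within each gene a sparse subset of common
    SNPs is chosen by L1-penalized (LASSO) regression with a cross-validated
    penalty, and the joint effect of the selected SNPs is then assessed with a
    partial F-test against a covariates-only reduced model, with gene-level
    Bonferroni correction. Includes an EMMA-style mixed-model partial F-test
    for related samples (twins, siblings), mass-univariate voxelwise F-maps
    with Benjamini-Hochberg FDR control, SNP-level quality control (minor
    allele frequency and exact Hardy-Weinberg filters), readers for VCF and
    rectangular dosage tables, and a simulator of LD-block-structured
    genotypes, phenotypes, voxel maps and family relatedness so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
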