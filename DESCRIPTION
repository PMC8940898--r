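Package: segmentScan
Title: Segment-Level Expression Heritability, Local Heritability and
    Mediated Causal Effects from Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region- and segment-level analysis of the genetic regulation of
    gene expression and of complex traits. Trains weighted cross-tissue
    elastic-net expression models restricted to a genomic segment, estimates
    local SNP heritability from GWAS summary statistics with an optimized
    (Ledoit-Wolf projected) linkage-disequilibrium matrix, performs
    summary-statistics gene-trait association and phenome scans, fits a
    penalized Mendelian randomization model robust to horizontal pleiotropy,
    decomposes GWAS effects into expression-mediated and indirect components
    (the pi_c statistic), and computes genetically determined expression
    scores for genotype panels including archaic genotype profiles. Includes
    synthetic-data generators reproducing the simulation designs used to
    validate the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Genetics, SNP, HeritabilityEstimation,
    StatisticalMethod, Regression
RoxygenNote: 7.3.3
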