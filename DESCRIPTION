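Package: uvbGweis
Title: Gene-Environment Interaction GWAS of Vitamin D Status with a
    Cumulative Weighted Ambient UVB Exposure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide gene-environment interaction studies of
    25-hydroxyvitamin D (25OHD) concentration using an individualized
    cumulative weighted ambient UVB dose (CW-D-UVB). Converts residential
    British National Grid coordinates and sampling dates into exposures
    from a gridded daily UVB dose product, performs variant- and
    sample-level genotype quality control (missingness, allele frequency,
    Hardy-Weinberg exact test, KING-robust kinship, heterozygosity),
    estimates per-variant marginal, main and interaction effects with
    model-based and heteroskedasticity-consistent covariance (1-df
    marginal, 1-df interaction and 2-df joint Wald tests), selects
    independent variants by LD clumping and stepwise conditional
    regression, builds marginal and interaction-aware genetic risk scores,
    and estimates SNP-heritability and genetic correlation by LD score
    regression, including exposure-stratified heritability. A synthetic
    data module generates LD-structured genotypes, seasonal UVB grids and
    phenotypes with known ground truth so that the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    VariantAnnotation,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
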