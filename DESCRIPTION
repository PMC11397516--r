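Package: AIOpred
Title: Genomic Prediction of Quantitative Traits from SNP-Derived
    Artificial Image Objects
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts quantitative traits from genome-wide biallelic SNP
    genotypes by encoding each accession as an artificial image object
    (one pseudo-colour channel per genotype state, cyclic row-major SNP
    layout), extracting population-structure features by block dictionary
    learning with orthogonal matching pursuit, and fitting an
    encoder-decoder convolutional network whose globally pooled feature
    maps feed an extreme gradient boosting regressor trained under mean
    absolute error. Influential SNPs are identified from dense regression
    attention (input-gradient saliency) maps aggregated to per-SNP scores
    and screened with Dunnett's many-to-one criterion, with genotype-class
    t-tests for phenotypic follow-up. Includes a Balding-Nichols style
    genotype and phenotype simulator with known causal architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    mvtnorm,
    xgboost,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    png,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-io.R'
    'aio.R'
    'dictionary.R'
    'features.R'
    'cnn.R'
    'model.R'
    'attribution.R'
    'synthetic.R'
    'pipeline.R'
    'zzz.R'
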