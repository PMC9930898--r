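Package: prsmr
Title: Polygenic Risk Score Construction and Mendelian Randomization
    with Spurious-Instrument Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing single-nucleotide polymorphism (SNP)
    selection strategies in genetic and polygenic risk scores.  Implements
    genotype quality control (minor-allele-frequency, call-rate,
    imputation-quality and stratified Hardy-Weinberg filters, KING-robust
    kinship pruning, sliding-window linkage-disequilibrium pruning,
    ancestry principal components), per-cohort marginal genome-wide
    association scans, fixed-effect inverse-variance meta-analysis,
    clumping-and-thresholding and penalized joint polygenic scores with a
    repeated stratified nested cross-validation harness, leave-one-out
    gene-prioritization weights for SNP selection, and one-sample
    Mendelian randomization with a resampling-based procedure that
    detects and removes spurious instruments using permutation-derived
    pseudo-SNPs.  A synthetic-data module generates linkage-structured
    multi-cohort case-control panels and confounded exposure-outcome
    datasets with known ground truth for validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
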