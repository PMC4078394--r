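Package: csgwas
Title: Compressed-Sensing Marker Selection for Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: L1-penalized regression for selecting trait-associated markers in
    genome-wide association studies, treated as a compressed-sensing problem.
    Provides a pathwise cyclic coordinate-descent lasso solver with warm starts
    and a theoretically motivated, noise-dependent penalty floor; simulation of
    standardized SNP genotype matrices (independent or block-correlated
    columns) and of phenotypes at a target narrow-sense heritability from
    sparse coefficient ensembles; selection-quality metrics including the
    normalized coefficient error, false positive rate, positive predictive
    value, and the observable median-P-value diagnostic; an explorer for the
    sparsity-undersampling (rho-delta) phase plane with detection of the
    transition from poor to complete selection and the asymptotic L1 phase
    boundary; and a single-marker (marginal regression) baseline. PLINK binary
    and delimited-text genotype input/output are supported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
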