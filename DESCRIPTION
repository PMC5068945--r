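Package: grmgwas
Title: Genome-Wide Association Scans with Genomic Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single- and multi-marker association scans for quantitative
    traits under a mixed linear model with a marker-derived genomic
    relationship matrix (GRM). Builds raw and mean-diagonal-scaled GRMs,
    estimates genomic and residual variance components by maximum
    likelihood through the eigendecomposition of the GRM, and computes
    ordinary and generalized least-squares marker scans, genomic BLUP,
    and mixed-model-equation solutions. Sherman-Morrison-Woodbury
    downdates deliver the inverse phenotypic covariance matrix after
    markers or eigenvectors are removed from the GRM at the cost of a
    single base inversion, including the corrected sampling variance of
    marker-out estimators. Population structure diagnostics include
    principal-component-adjusted scans and classical and nonmetric
    multidimensional scaling with the STRESS goodness-of-fit criterion.
    A structured genotype/phenotype simulator supports end-to-end
    testing and power studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
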