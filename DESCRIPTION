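Package: txatlas
Title: Multiscale Transcriptome Atlases: Recursive Clustering, Entropy-Based
    Heterogeneity and Hierarchical Multilabel Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and exploit multiscale transcriptional atlases from
    bulk expression cohorts. Provides scale-adaptive recursive clustering
    (variance filtering, nonlinear embedding and density-based cluster search
    optimised per level by the silhouette coefficient) that yields a hierarchy
    of expression classes; per-gene transcriptional entropy via fixed-bandwidth
    Gaussian kernel density estimation with reference normalisation,
    mean-expression adjustment and robust class summaries; a
    population-weighted split score (PaWS) over the hierarchy; SimGIC-weighted
    hierarchical similarity scores between membership-probability vectors; a
    hierarchical multiclass-multilabel classifier with ensemble averaging,
    parent-child probability consistency enforcement and piecewise-linear
    probability recalibration; and a seeded synthetic-cohort generator
    (negative-binomial counts with nested marker blocks, library-size
    variation, sample mixing and binomial count thinning) so every component
    is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table,
    cluster,
    uwot,
    glmnet,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
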