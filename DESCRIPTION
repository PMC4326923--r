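Package: AgeTrends
Title: Temporal Transcriptome Trajectories Across Age Groups
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of bulk RNA-seq time courses over ordered age
    groups, modelled on short-lived vertebrate aging studies. Detects
    differentially expressed genes as the intersection of three independent
    per-gene tests (negative-binomial Wald, rank-sum, permutation fold-change)
    over all pairwise age-group comparisons with FDR control; clusters
    standardized temporal profiles by fuzzy c-means with the cluster number
    chosen by a vote of validity indices; classifies U- and bell-shaped
    trajectories by quadratic fitting and locates their inversion ages;
    performs hypergeometric gene-set enrichment with kappa-based term grouping
    and cross-dataset term intersection; builds thresholded Pearson
    coexpression networks with hub and component analysis, overall and within
    age strata; and ordinates samples by classical multidimensional scaling.
    Includes a negative-binomial simulator of archetypal temporal profiles
    with ground-truth labels for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
biocViews: GeneExpression, RNASeq, TimeCourse, Clustering, Network,
    DifferentialExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'AgingExperiment-methods.R'
    'clustering.R'
    'deg.R'
    'enrichment.R'
    'io.R'
    'network.R'
    'ordination.R'
    'pipeline.R'
    'shapes.R'
    'simulate.R'
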