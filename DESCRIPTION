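Package: chronoclass
Title: Classification of Developmental microRNA Expression Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling and classifying microRNA expression across
    broad developmental age categories (fetal, young, adult) from dual-channel
    microarray and pooled TaqMan qPCR data. Implements dual-scan dynamic-range
    merging, feature-level quality filtering and LOWESS normalization,
    per-gene ANOVA with backward model selection over the thirteen weak
    orderings of the three age-category means, simulation-based (SAM-like)
    false discovery rate calibration, permutation tests for annotation
    enrichment within expression classes, correlation-metric hierarchical
    clustering, and a 2^-ddCt relative-quantification screen with a
    two-standard-deviation fold-change filter. A synthetic-data generator with
    known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
biocViews: Software, GeneExpression, Microarray, qPCR, Normalization,
    Classification, MultipleComparison
Config/testthat/edition: 3
RoxygenNote: 7.3.3
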