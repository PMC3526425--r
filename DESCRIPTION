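Package: ligap
Title: Lineage Commitment Analysis of Multi-Condition Expression Time
    Courses with Gaussian Processes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares gene-expression time courses measured under two or
    more conditions (for example T helper cell polarizing cultures) by
    Bayesian model selection over all set partitions of the condition
    labels. Each partition groups conditions that share one latent
    temporal profile, modelled by Gaussian-process regression with a
    non-stationary neural-network covariance function; the analytic
    marginal likelihood of every partition is converted into posterior
    probabilities, and per-condition differential-regulation scores are
    derived by summing the posteriors of partitions in which a condition
    is separated from all others. Includes fold-change calling on fitted
    profiles, profile plots with 95 percent credible bands, PCA of score
    vectors, complete-linkage clustered heat maps of standardized fitted
    profiles, transcription-factor binding-site enrichment by one-sided
    Fisher's exact test, and a synthetic time-course generator with known
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: TimeCourse, DifferentialExpression, GeneExpression,
    Bayesian, Regression
RoxygenNote: 7.3.3
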