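Package: retinotwin
Title: Twin-Design Heritability Analysis of Retinotopic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating genetic contributions to the fine-grained
    organization of retinotopic maps in a classical twin design. The package
    simulates twin cohorts of population receptive field (pRF) maps with
    controlled intra-pair correlations, forward-models wedge-and-ring pRF
    mapping time courses and fits the two-dimensional Gaussian pRF model with
    a coarse-to-fine scheme, and implements the full inferential pipeline:
    Jaccard overlap of region delineations, multivariate map similarity,
    de-meaned intra-pair correlations (Spearman and circular), the
    Falconer-style correlation difference with bootstrap confidence intervals
    and permutation nulls, a moment-based multidimensional heritability
    estimator, and power simulations for the correlation-difference test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
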