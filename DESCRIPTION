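Package: pathcnn
Title: Interpretable Convolutional Networks on Multi-Omics Pathway Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts gene-level multi-omics matrices (expression, copy number,
    methylation) into per-sample "pathway images" via per-pathway, per-omics
    principal component analysis, orders pathway rows so correlated pathways
    are adjacent, trains a small convolutional network to classify long-term
    versus non-long-term survivors under repeated stratified cross-validation
    with class weighting, and interprets the fitted model with Grad-CAM class
    activation maps: per-sample class-difference maps are compared between
    survival groups pixel-wise with Wilcoxon rank-sum tests and Bonferroni
    correction, significant hot spots are extracted as connected components,
    and single-pixel findings are followed up with Kaplan-Meier median-split
    log-rank tests. Includes a synthetic multi-omics cohort generator with
    planted pathway-level survival signal so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    survival,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
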