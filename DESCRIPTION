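Package: cidrgn
Title: Comprehensive Differential Gene Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene subnetworks whose regulatory structure differs
    between two phenotypes by combining three sources of dissimilarity:
    differences in expression levels (the SAM-GS gene-set statistic),
    differences in the regulatory effects carried by estimated network edges,
    and Jaccard dissimilarity of node neighbourhoods. Networks are estimated
    by per-target lasso regression, significance is assessed by a permutation
    scheme with full network re-estimation, and an extension to
    sample-specific (cell-line-characteristic) networks uses kernel-weighted
    varying-coefficient estimation driven by a scalar modulator. Includes a
    Gaussian graphical model simulator (random, band, cluster, scale-free and
    hub precision-matrix structures) and a Monte Carlo benchmarking framework
    with the comparator statistics SAM-GS and GSCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
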