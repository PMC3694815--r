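Package: pmrgwas
Title: Penalized Multiple Regression for Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse penalized multiple regression for case/control and
    quantitative genome-wide association studies. Implements a
    minorize-maximization coordinate-ascent solver for penalized
    generalized linear models under five sparsity penalties (Lasso,
    Adaptive Lasso, LOG, NEG, MCP), data-adaptive tuning-parameter
    search with AIC model selection under a sample-size-dependent
    model-size bound, post-hoc likelihood-ratio scoring with
    correlation pruning of selected markers, single-marker and
    conditional association scans with genomic-control diagnostics,
    PLINK transposed-text input/output, a liability-threshold
    case/control simulator with linkage-disequilibrium-blocked
    genotypes, and power-at-FDR evaluation against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
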