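Package: stocktactics
Title: Attribution of Fishery Stock Status to Management Tactics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for snapshot analyses of fishery stock status relative to
    management targets. Simulates multi-stock groundfish fleets under Schaefer
    surplus-production dynamics with harvest control rules and implementation
    error; estimates MSY-based reference points by fitting a Schaefer model to
    catch and biomass series; computes ten per-stock performance measures over
    a recent five-year window, including a downside-risk semi-deviation of log
    status ratios; attributes variation in those measures to management
    covariates with a bagged regression-tree ensemble (out-of-bag error,
    permutation importance, partial dependence, categorical marginal means);
    screens predictors with generalized variance inflation factors; and
    quantifies foregone revenue from catches below allowable limits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
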