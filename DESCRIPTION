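Package: wkmsvm
Title: Weighted K-Means Support Vector Machines with Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binary classification with support vector machines whose hinge
    loss carries per-sample weights, solved through the weighted Wolfe dual
    by a sequential minimal optimization (SMO) solver. Includes K-means
    prototype reduction (global majority-vote and by-class variants),
    AdaBoost.M1-style reweighting of training units or cluster centers,
    cross-validated tuning of the regularization constant, a rank-based
    probe filter for methylation-style feature matrices, and a reproducible
    simulation harness for two-class Gaussian benchmarks.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    e1071,
    optparse,
    rpart,
    class,
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
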