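Package: laguerreGC
Title: Laguerre-Based Conditional Granger Causality and Network
    Inference Benchmarking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conditional Granger causality estimation in which the lagged
    regressors of the classical multivariate autoregressive formulation
    are replaced by a first-order Volterra-Wiener expansion over
    discrete-time orthonormal Laguerre functions, so that a single decay
    parameter captures arbitrarily long signal memory without increasing
    the model order. Includes random directed ground-truth network
    generation at controlled density, a coupled stochastic node simulator
    with 1/f long-range-correlated noise and randomly delayed integral
    couplings, ROC/AUC benchmarking of the Laguerre estimator against the
    classical lagged baseline, and post-processing operators for
    band-limited power-envelope connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: TimeCourse, Network, GraphAndNetwork, StatisticalMethod
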