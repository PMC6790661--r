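Package: psarank
Title: Rank Probabilities and Acceptability Analysis for Probabilistic
    Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes Monte Carlo probabilistic sensitivity analysis
    (PSA) samples from multi-option health-economic decision models. Computes
    net monetary benefit at a willingness-to-pay threshold, rank-probability
    matrices, cumulative rankograms, SUCRA, mean/median/IQR rank,
    first-order stochastic dominance between options, cost-effectiveness
    acceptability curves (CEAC) and the acceptability frontier (CEAF), and
    the mean-outcome efficiency frontier with strict and extended dominance
    and incremental cost-effectiveness ratios. Includes a Gaussian-copula
    synthetic PSA generator with packaged scenarios, Table-style reports,
    rankogram and CEAC plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
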