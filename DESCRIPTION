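Package: grnic
Title: Sparsity Selection for Gene Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the best network from a sparsity sweep of candidate gene
    regulatory networks (GRNs) inferred from perturbation expression data.
    Each candidate is scored with the GRN Information Criterion (GRNIC), the
    sum of a normalized regulator-count penalty and a normalized badness of
    fit obtained by reconstructing the measured log2 fold-change expression
    from the candidate network via a singular-value-safeguarded pseudoinverse.
    Ships a linear steady-state benchmark simulator (stable random networks,
    single-knockdown perturbation designs, replicate concatenation,
    SNR-controlled Gaussian noise) and three inference backends (lasso paths,
    ridge with cutoffs, tree-ensemble importances with reversed edge
    direction), so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
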