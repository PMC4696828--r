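Package: mirlens
Title: A Dry Lab for Inferring miRNA-mRNA Regulatory Relationships from
    Matched Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microRNA (miRNA) to messenger RNA (mRNA) regulatory
    relationships from matched expression profiles measured on the same
    samples.  Implements eleven scoring methods spanning correlation and
    dependence measures (Pearson, Spearman, Kendall tau-b, distance
    correlation, Hoeffding's D, the randomised dependence coefficient),
    mutual information, penalised regression (lasso and elastic net),
    causal effect estimation (PC-stable structure learning followed by
    IDA adjustment regressions) and a pseudo-knockout Z-score.  Provides
    Borda rank-aggregation ensembles, masking by sequence-based target
    predictions, validation of top-k predictions against confirmed
    interactions and miRNA perturbation experiments, method comparison by
    ranking scores, a synthetic-data generator with planted regulation so
    every stage runs offline, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
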