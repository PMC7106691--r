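Package: himpair
Title: Hierarchical Integrative Modeling of Disease-Associated miRNA-mRNA Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies miRNA-mRNA pairs associated with a binary disease
    status (for example tumor versus matched adjacent-normal tissue) from
    paired expression matrices using a two-level hierarchical integrative
    model. Features are prefiltered with TMM normalization, log transforms,
    paired t-tests and Benjamini-Hochberg false discovery rate control. A
    mechanistic submodel then regresses each significant mRNA on all
    significant miRNAs with a lasso penalty, decomposing it exactly into a
    miRNA-driven linear predictor and a residual; a clinical submodel fits a
    lasso-penalized logistic regression of disease status on the linear
    predictors, residuals, and leftover molecules, and selected linear
    predictors emit miRNA-mRNA pairs. Includes a pairwise-correlation
    baseline, a paired tumor/normal count simulator with known ground truth,
    recovery scoring, and a reproducible command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    edgeR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
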