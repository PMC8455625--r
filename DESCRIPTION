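Package: pharmsig
Title: Pan-Cancer Elastic-Net Drug-Response Signatures from Cell-Line
    Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains, locks, and applies per-drug elastic-net treatment
    response signatures from cell-line DNA mutation and RNA expression
    data, in the style of pan-cancer pharmacogenomic screens.  Gene
    expression (log2 FPKM, median-scaled) and binary protein-altering
    mutation status on a cancer-gene panel are combined into a shared
    feature space; per-drug models are tuned by 10-fold cross-validation
    over an alpha/lambda grid and locked for platform-independent
    prediction of Z-scored IC50 (sensitivity scores, lower = more
    sensitive).  Includes the downstream validation statistics
    (per-drug Pearson correlation with external drug response plus
    Benjamini-Hochberg FDR, biomarker group comparisons, and
    treatment-by-score interaction testing for predictive-biomarker
    claims), a pan-cancer mutation-drug association scan with a
    tumor-site covariate, a synthetic cohort generator with stored
    ground truth, and a command-line interface wiring the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
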