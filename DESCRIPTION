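Package: metaboconsensus
Title: Consensus Biomarker Selection for Case-Control Plasma Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A four-branch data-mining pipeline for untargeted LC-HRMS
    plasma metabolomics of case-control cohorts. Implements pooled-QC based
    feature quality filtering (coefficient of variation, dilution-series
    linearity, completeness), LOESS drift correction, log/Pareto
    transformation, univariate Wilcoxon/Benjamini-Hochberg/fold-change
    selection, orthogonal projection to latent structures discriminant
    analysis (OPLS-DA) with VIP, S-plot and cross-validation diagnostics,
    a bootstrapped wrapper feature selector over PLS-DA, random forest and
    linear SVM classifiers, resampled LASSO stability selection with
    AUC-gated model retention, and the consensus rule that combines the
    four selections into a final metabolite signature. Ships a synthetic
    cohort generator emulating interleaved pooled-QC injections,
    instrumental drift and a QC dilution series so the whole pipeline is
    testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
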