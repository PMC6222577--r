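Package: panelmark
Title: Biomarker Candidate Discovery from Strain-Panel and Case-Control Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for nominating circulating disease biomarkers from a
    reference panel of inbred mouse strains. Implements two-group
    differential expression with empirical-Bayes moderated t-statistics and
    Benjamini-Hochberg adjustment, per-strain transcript-trait correlation,
    overlay-based candidate prioritization, cross-species concordance
    against a human differential-expression table, and case-control
    validation statistics (pooled/Welch t-tests from raw data or printed
    summaries, Fisher exact tests, Spearman rank correlation, and iteratively
    reweighted least-squares logistic regression with Wald odds-ratio
    intervals). A synthetic-data module simulates strain-panel expression
    with planted fold changes, trait links with known correlations, and
    case-control cohorts with planted covariate effects, so the whole
    pipeline is testable end to end with known ground truth.
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
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
biocViews: DifferentialExpression, Transcriptomics, Regression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
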