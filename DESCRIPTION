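Package: bgfc
Title: Basal Ganglia Functional Connectivity and Fatigue in Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for basal-ganglia functional connectivity and
    fatigue in a block-design alertness-motor fMRI paradigm. Takes
    AAL-parcellated (116-region) BOLD time series or NIfTI volumes through
    nuisance regression, 0.01-0.08 Hz zero-phase bandpass filtering, task-wise
    segmentation, Pearson/Fisher-z connectivity, and local/global basal-ganglia
    connectivity statistics; merges per-block reaction-time and grip-force
    fatigue measures; and produces group-level report tables (t-tests with
    Cohen's d, 2x2 mixed ANOVA with partial eta squared, correlation tables,
    Benjamini-Hochberg FDR). Includes a calibrated synthetic-cohort generator
    that emulates the statistical structure of a two-group (multiple sclerosis
    vs healthy control) fatigue study so that every stage is testable without
    access to raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
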