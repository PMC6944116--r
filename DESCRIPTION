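Package: uvg2pipe
Title: Polysome Profiling Candidate Selection, Checkpoint Screen Scoring,
    and Pathway Deregulation Scores for the UV-G2 Checkpoint
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for studying the postreplication-repair
    UV-G2 checkpoint through three linked stages: empirical-Bayes moderated
    differential polysome-loading analysis with fold-change and B-statistic
    candidate selection (including G2-phase subtraction and cross-platform
    intersection), per-well scoring of high-content siRNA and
    overexpression screens (DNA-content cell-cycle fractions, RPA focus
    statistics with Tukey HSD comparisons, and confidence tiering), and a
    principal-curve pathway deregulation score (PDS) related to UV
    signature mutation load in a melanoma-like cohort. Synthetic-data
    generators with planted, recoverable structure stand in for microarray,
    RNA-seq, imaging, and cohort inputs so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
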