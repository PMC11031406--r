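Package: ctdnaMRD
Title: Matched-WBC-Informed ctDNA Variant Origin Classification and
    Minimal Residual Disease Trajectory Analysis
Version: 0.9.0
Authors@R:
    person("ctdnaMRD", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for tumor-agnostic liquid-biopsy analysis in clinical
    trials: a matched white-blood-cell-informed decision tree that assigns
    plasma variants a germline, clonal-hematopoiesis or tumor origin using
    COSMIC hotspot annotation and error-corrected super-mutant counts;
    longitudinal ctDNA detection, cell-free tumor load and clearance
    trajectory calling across trial timepoints; pathological tumor
    regression grading; the associated outcome statistics (Kaplan-Meier
    with Greenwood log-log confidence intervals, log-rank tests, exact
    binomial intervals, Fisher exact and Wilcoxon rank-sum tests); Bayesian
    beta-binomial safety and feasibility monitoring rules; and a fully
    synthetic cohort generator with ground-truth bookkeeping so every
    pipeline stage is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
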