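Package: phenoequiv
Title: Equivalence Testing of Rule-Based Diabetes Computable Phenotypes
Version: 0.1.0
Authors@R:
    person("Open", "Phenotyping", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing rule-based computable phenotypes (CPs) for
    type 2 diabetes applied to patient-level electronic health record (EHR)
    extracts. Implements two surveillance phenotypes -- one driven by
    laboratory results, diagnosis codes and medications with explicit
    type 1 exclusion rules, and one two-step wide-net/codes-only classifier
    -- together with stratified prevalence estimation and the two one-sided
    tests (TOST) procedure for equivalence of two independent proportions
    with a fixed margin in percentage points. A synthetic EHR generator with
    known true disease labels and configurable observation (capture)
    processes makes every pipeline stage testable without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
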