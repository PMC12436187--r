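Package: foxg1strat
Title: Functional-Assay Severity Stratification for FOXG1 Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the severity of brain anomalies caused by
    intragenic FOXG1 variants from functional-assay evidence. Implements the
    FOXG1 clinical severity score (CSS, mean of 17 ordinal items) and the
    brain-MRI severity score (MRI SS, sum of five imaging items), normalizes
    raw readouts from three functional assays (western-blot protein
    expression, dual-luciferase COUP-TFI repression, and in utero
    electroporation neuronal-migration zone counts) into categorical calls,
    and applies a three-stage decision cascade that maps each variant's
    assay profile to a predicted severity band. Includes a packaged 14-case
    cohort with published clinical and assay categorizations, stage-wise
    sensitivity evaluation against MRI ground truth, and a synthetic-cohort
    generator so that the entire pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
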