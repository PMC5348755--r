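Package: cotrend
Title: Method-Comparison Statistics for Cardiac Output Monitor Validation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating continuous cardiac-output monitors against a
    reference method such as transpulmonary thermodilution: Bland-Altman
    agreement with correction for multiple measurements per subject,
    percentage error, four-quadrant and polar-plot trending analysis with
    exclusion zones, fluid-responsiveness classification and comparison of
    correlations, descriptive summaries with baseline contrasts, and a
    synthetic-study generator with known ground truth so the whole pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
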