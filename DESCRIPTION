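Package: phenoval
Title: Design-of-Experiments Optimization and ICH Validation for
    Phenolic Extraction and HPLC Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for optimizing ultrasound-assisted extraction of leaf
    polyphenols and validating an external-standard HPLC-DAD
    quantification method. Covers two-level fractional factorial
    screening with Dong's critical-effect significance rule, central
    composite designs with quadratic response-surface fitting and
    single- or desirability-based optimization, ICH-style method
    validation (calibration linearity with Mandel's fitting test,
    Cochran's C homogeneity test, repeatability and intermediate
    precision with Horwitz acceptability limits, recovery-based
    accuracy, detection and quantification limits), conversion of peak
    areas to mass fractions with censoring-aware totals, and
    correlation/principal-component analysis of phytochemical
    composition matrices. Seeded synthetic-data generators emulate
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
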