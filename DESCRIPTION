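Package: pcospectrum
Title: Rule-Based EHR Phenotyping and Polygenic Risk Analysis of the PCOS Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify polycystic ovary syndrome (PCOS) patients in
    electronic health record (EHR) extracts with four nested rule-based
    phenotyping algorithms built from ICD9/ICD10 code sets and clinical-note
    keywords, to evaluate those algorithms with chart-review style metrics
    (positive/negative predictive value, sensitivity, specificity,
    prevalence), to clean and age-adjust laboratory values with a rank-based
    inverse normal transformation, and to test the association between a
    PCOS polygenic risk score and algorithm-defined case status with
    matched logistic regression and Nagelkerke pseudo-R-squared. Includes a
    synthetic EHR population generator with a liability-based genetic
    model so the full pipeline can be exercised and validated without
    access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
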