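Package: pacvalid
Title: Validation of Hospital Discharge Ascertainment of Pregnancy-Associated Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for validating administrative hospital discharge data as a
    source of incident pregnancy-associated cancer ascertainment against a
    population cancer registry gold standard. Builds pregnancy exposure windows
    from maternity records, phenotypes ICD-10-AM diagnosis codes into clinical
    cancer groups, constructs registry and hospital (index and all-admission)
    case sets, and computes sensitivity, specificity, predictive values with
    exact Clopper-Pearson intervals, incidence rates, rate ratios,
    false-positive adjudication (prevalent versus miscoded type) and
    admission-versus-registration timing distributions. Includes a seeded
    synthetic linked-cohort generator emulating the statistical structure of
    linked maternity, hospitalisation and registry collections so the full
    pipeline is testable without access to identifiable health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
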