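Package: pedhtn
Title: Guideline-Based Pediatric Hypertension Surveillance from Outpatient
    Blood Pressure Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A table-driven pipeline for surveillance of pediatric
    hypertension in outpatient electronic health records. Cleans
    longitudinal blood-pressure visit panels with attrition accounting,
    converts anthropometrics to z-scores with the LMS method, resolves
    age-sex-height blood-pressure percentile thresholds under the 2004
    Fourth Report and the 2017 American Academy of Pediatrics guideline,
    classifies each person-year of age as hypertensive, elevated, or
    normal, and computes event rates per 1000 persons, annual trends,
    Cohen's kappa inter-guideline agreement with confidence intervals,
    body-mass-index categories, medical-complexity levels from diagnosis
    histories, and odds-ratio association analyses. Ships a synthetic
    electronic-health-record generator with known ground truth so every
    stage is testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
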