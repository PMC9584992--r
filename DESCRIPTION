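Package: gfragree
Title: Agreement Between Measured and Estimated Glomerular Filtration Rate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating how well estimated glomerular filtration
    rate (eGFR) equations reflect measured GFR (mGFR) in adult kidney-disease
    cohorts, with defaults modelled on autosomal dominant polycystic kidney
    disease (ADPKD). Provides a plug-in registry of published eGFR equations
    (MDRD, CKD-EPI, Cockcroft-Gault, FAS, Lund-Malmo, CAPA, Hoek, Larsson),
    body-surface-area un-adjustment, iohexol plasma-clearance computation by
    the slope-intercept method with one-pool correction, agreement statistics
    for continuous method comparison (concordance correlation coefficient,
    total deviation index, coverage probability, bootstrap bounds),
    CKD-threshold misclassification reports around treatment cut-offs, and a
    seeded synthetic-cohort generator so the full analysis runs without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
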