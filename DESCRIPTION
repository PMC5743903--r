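Package: sdreburden
Title: Claims-Based Burden Analysis of Severely Drug-Refractory Epilepsy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenotypes severely drug-refractory epilepsy (SDRE) from
    longitudinal statutory health-insurance claims (at least four distinct
    anticonvulsant substances, ATC class N03A, dispensed within a rolling
    18-month window plus a coded G40 epilepsy diagnosis), builds an
    age/sex-matched epilepsy-free comparison cohort at a configurable ratio,
    and quantifies hospitalization, procedures, prescriptions, comorbidity,
    mortality and direct costs over a one-year baseline and three 365-day
    follow-up years anchored at the fourth-substance index date. Includes a
    seeded synthetic claims generator with known ground truth, a
    self-contained statistical kernel (Pearson chi-square for 2x2 tables and
    the Kaplan-Meier product-limit estimator), and a one-command pipeline
    that writes report tables with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, grDevices, graphics
Suggests: testthat (>= 3.0.0), withr, survival, optparse
Config/testthat/edition: 3
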