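Package: ehrepisodes
Title: Construct Episodes of Illness and Morbidity Rates from Primary Care EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning routinely recorded general-practice electronic
    health record data (episodes of care, single coded encounters, and
    diagnosis-coded prescriptions, all coded in ICPC-1) into episodes of
    illness, and for computing incidence and prevalence rates per 1000
    person-years from those episodes. Episodes of illness are built per
    patient and diagnosis code by grouping dated contacts with a
    category-specific contact-free interval and appending half of that
    interval after the last contact as the estimated recovery time; chronic
    diseases form a single episode ending only at death or end of
    observation. Person-time denominators are derived from quarterly
    registration (enrollment claim) records. A reproducible synthetic EHR
    generator emulates common recording imperfections (open-ended or
    duplicated episodes of care, encounters miscoded into the wrong episode,
    loose single encounters, registration churn) so that the whole pipeline
    can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
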