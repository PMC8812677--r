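Package: rtiepisodes
Title: Episode Construction and Remote-Care Trends for Respiratory
    Tract Infection Contact Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds care episodes from person-level health-care contact
    registries for respiratory tract infections (RTI): index contacts are
    defined by a 181-day diagnosis-free clean period and follow-up
    contacts by a 30-day attribution window, with contacts classified by
    modality (in-person, remote with a traditional provider, or private
    telemedicine provider).  Provides per-1000-inhabitant and per-index
    aggregation, monthly trend series, regression-based difference tests
    with heteroskedasticity-robust standard errors, and Pearson
    chi-squared tests of follow-up-contact composition.  Includes a
    seeded synthetic contact-registry generator with ground-truth labels
    so the full pipeline can be validated without access to regional care
    registers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
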