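Package: omopsurvey
Title: Harmonise Longitudinal Mental-Health Survey Data into the OMOP Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for transforming snowflake-schema longitudinal
    mental-health survey data (households, individuals, waves, instruments, item
    responses) into OMOP Common Data Model tables. Provides a file-backed staging
    data model, a synthetic multi-study data generator with controlled error
    injection, local-concept vocabulary minting in the 2-billion identifier range
    with paired concept relationships, curated variable-to-concept mapping with a
    review queue, a four-phase dependency-ordered ETL with an error log and
    execution audit trail, a declarative Kahn-framework data-quality check engine
    (conformance, completeness, plausibility), and downstream analytics: earliest-
    event cohort construction, demographic characterisation, incidence rates per
    1,000 person-years, and event-cohort pathway sequencing. Psychometric
    instrument scoring (PHQ-9, GAD-7, EPDS, DASS-21, CES-D, PCL-5, PSQ) is built
    in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
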