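Package: cdmaudit
Title: Completeness Auditing for OMOP CDM-Style Clinical Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Practical completeness assessment for relational clinical
    datasets laid out like the OMOP Common Data Model. Provides a
    three-component audit: structural assessment of table availability,
    row counts and storage volume; a declarative rule engine for
    missing/special-value, unmapped-concept, temporal-discontinuity and
    value-range checks; and descriptive completeness/diversity profiling
    of demographics, vocabularies, visit types and top clinical concepts.
    A seeded synthetic CDM generator with exact-count defect injection
    makes every check verifiable without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    DBI,
    RSQLite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
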