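Package: phitriage
Title: Staged Triage of Heterogeneous Files for Personal Health Information Leaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based pipeline that scans directories of files of unknown
    type and flags documents disclosing personal health information (PHI),
    i.e. documents that both identify an individual and reveal specifics of
    that individual's health. Shallow stages (duplicate removal, published
    title lookup, text extraction, character n-gram language identification,
    and publishable-content keyword triage) discard files that cannot leak
    PHI; the remaining files are screened with lexicon and pattern based
    detectors for personally identifiable information (names, dates, phone
    and health-card numbers, emails, postal codes, places, organizations)
    and for patient-oriented health terms (diseases, symptoms, procedures,
    drugs). Includes the binomial sampling model used to audit discarded
    files and bound the false-negative rate, and a seeded synthetic corpus
    generator for end-to-end evaluation without real file-sharing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
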