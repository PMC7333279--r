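Package: cdemdr
Title: Composite Common Data Elements with Constraint Validation for
    Metadata Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models atomic and composite common data elements (CDEs) in the
    style of an ISO/IEC 11179 metadata registry, extended with hybrid and
    variable atomic subtypes, general/repeated/dictionary composite kinds,
    and a prefix-notation constraint language (Operated, Required,
    Dependent, Ordered and dictionary rules) evaluated under three-valued
    logic.  Provides a record and table validation engine with structured
    findings, dictionary-backed unit and normal-range checking for
    laboratory results, metadata reuse and integration metrics across
    document corpora, JSON/CSV registry and record interchange, a
    deterministic synthetic-fixture generator with planted ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
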