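Package: chemxref
Title: Chemical Structure Cross-Referencing and Identifier Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An embeddable registry for cross-referencing small-molecule
    identifiers across chemical databases, using the Standard InChI as the
    canonical structure key. Sources deposit three-column identifier dumps
    (src_compound_id, Standard InChI, Standard InChIKey); the engine filters
    them through a fixed set of integrity rules, registers each distinct
    structure once under an immutable integer identifier, and tracks every
    identifier-to-structure assignment across releases as current or
    obsolete without ever deleting history. Query functions resolve any
    identifier, InChI or InChIKey to its structurally equivalent identifiers
    in all registered sources, build compound-page URLs, and produce whole
    source-to-source mapping tables. A synthetic dump-history generator and
    a brute-force replay oracle make the full loading and querying life
    cycle testable without network access, and a command-line interface
    exposes the registry to shell pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
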