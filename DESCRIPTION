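Package: kgmltune
Title: Parsing, Correction, and Context-Specific Tuning of KEGG KGML Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses KEGG pathway KGML files into an explicit graph model of
    entries and relations, detects and repairs common inconsistencies in
    signaling pathway markup (compound-mediated protein interactions,
    reversed binding directions, unexpanded protein-complex group nodes),
    generates biological-context-specific pathway variants by tissue-specific
    expression filtering and by protein-protein-interaction based drill-down
    of paralog nodes, and writes the result back out as valid KGML with every
    modification tracked in machine-readable log records.  Includes
    deterministic synthetic-fixture generators with planted, counted motifs
    and a command-line front end covering the retrieve-correct-tune-save
    workflow.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
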