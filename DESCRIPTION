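Package: pathwaycv
Title: Controlled Vocabulary Names for Pathway Entities and Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic generation of concise, unambiguous controlled
    vocabulary (CV) names for the molecular entities of curated biological
    pathways (modified peptides, small molecules, complexes, defined and
    candidate sets) and for pathway events (reactions), in the style used by
    the Reactome knowledgebase. Provides a recursive-descent parser that
    round-trips CV names back into structured entity trees, a rule-based
    reaction classifier mapping reactions onto event categories (binding,
    dissociation, transport, catalysis and friends), shortened diagram
    labels for protein-family sets, a JSON entity-document format with
    tab-separated lookup tables for modification prefixes, small-molecule
    abbreviations and Gene Ontology molecular-function verbs, plus a
    synthetic fixture generator and batch rename auditing for curation
    quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
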