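Package: regevents
Title: Ontology-Based Extraction of Gene-Regulation Events from Dependency-Parsed Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts explicit gene-regulation events from dependency-parsed
    biomedical text by loosely matching syntactic-semantic paired patterns in a
    bottom-up, compositional way, deduces implicit events with forward-chaining
    inference rules (modus ponens over P -> Q rules, with NXOR polarity
    composition and cross-sentence evidence combination) grounded in a miniature
    Gene Regulation Ontology, and emits database-ready regulatory-network
    records matching semantic templates. Includes dictionary-based named-entity
    recognition with grounding identifiers, a CoNLL-U reader, standoff/JSON/edge
    writers, an evaluation module, and a seeded synthetic-corpus generator with
    gold annotations for end-to-end testing of the pipeline and of the
    with/without-inference ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
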