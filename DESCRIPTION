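Package: icekb
Title: Ontology-Based Biomedical Knowledge-Base Construction with
    Explicit Information Content Entities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a queryable RDF knowledge base from heterogeneous
    biomedical source files by explicitly separating information content
    entities (databases, records, fields, field values, identifiers) from
    the biomedical concepts they denote. Source records are converted to an
    ICE triple graph with deterministic SHA-1-minted URIs, identifier
    identity is resolved across sources with type-guarded exact-match
    extraction and union-find closure into disjoint identifier sets, and
    declarative forward-chaining rules generate OBO-grounded biomedical
    concept (BIO) representations -- all-some restriction subclasses for
    annotations, interactions and pathways -- with full record-level
    provenance, replayable derivations, and quality-control queries that
    detect inconsistent source mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
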