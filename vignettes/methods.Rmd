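---
title: "Methods: ICE/BIO knowledge-base construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICE/BIO knowledge-base construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icekb)
```

## The model

`icekb` treats semantic integration of biomedical databases as a staged,
monotone construction over an RDF triple graph with two strictly separated
partitions.

**ICE (information content entities).** Every informational artifact of a
source — the database schema, each record, each field, each field value, and
each identifier — is represented explicitly. A record is linked to its
schema by `kiao:has_template` and to its field values by `obo:has_part`
(record-centric direction); a field value is defined by exactly three
triples: a type assertion against its schema's field-value class, a
`kiao:has_template` link to its field, and the value itself (a canonical
identifier URI for identifier-bearing fields, a plain literal otherwise).
Because field-value URIs are pure functions of (field, value), a value shared
by many records is one node, and its three defining triples are stored once.
This is the entire point of the representation: nothing about the source is
paraphrased away, identifiers are never conflated with the records that carry
them or the concepts they name, and the informational layer later serves as
provenance.

**BIO (biomedical concepts).** Genes, proteins, drugs, processes,
interactions and pathways live in a second partition grounded in ontology
classes. Everything on this side is generated, never hand-asserted, and every
generated assertion is a *fresh subclass* of an ontology class rather than an
assertion on the ontology class itself — so inconsistent sources produce
parallel subclasses, not contradictions. The only predicates allowed to
cross from ICE to BIO are the aboutness relations `iao:denotes`,
`iao:mentions` and `iao:is_about`; the package asserts this as a testable
graph invariant.

**Assumptions.** Sources are record-shaped (delimited rows or GAF lines);
mappings between identifiers are intended to denote sameness of the
underlying concept (the type guards exist precisely because this intent is
often violated); ontologies supply a subclass hierarchy that is loadable
up-front; and build inputs fit in memory — the graph is a `data.table`, not
a triplestore server.

## Construction stages

1. **Ontology loading.** The class/relation vocabulary loads verbatim; a
   subclass cycle is logged but not rejected (validation is the ontology
   maintainer's job, and rules only ever *walk* the hierarchy).
2. **RDFization.** Schema-driven readers parse each file; rows with the
   wrong shape or unknown identifier dialects are quarantined with logged
   warnings, never silently dropped. Identifier canonicalization happens
   here, so the graph never contains a lexical dialect.
3. **Ontology identifier ICEs.** Each ontology class in a registered
   identifier space (GO terms, taxa) receives an identifier ICE that
   `iao:denotes` it, so records can reference ontology concepts without ever
   holding a BIO URI.
4. **Bootstrap entity typing.** Knowing whether a dbXref target is "the same
   thing" requires knowing what it denotes, but concepts do not exist yet.
   The cycle is broken by asserting, per identifier space, what *kind* of
   concept its identifiers will denote: `X kiao:denotesSubClassOf Z`, a
   macro expanded deterministically into `X iao:denotes Y` and
   `Y rdfs:subClassOf Z`.
5. **Type-guarded exact-match extraction.** Mapping specs name a schema and
   a left/right field pair; candidate pairs are kept only when both guard
   types are identical or one subsumes the other in the loaded hierarchy.
   Filtering is the success path: the gene↔protein and gene↔drug pairs a
   dbXref field offers are counted and logged, not linked.
6. **Identifier sets.** Exact-match links are closed into disjoint sets with
   union–find (union by size, path halving); identifiers with no links form
   singletons, so every typed identifier yields a denoted concept
   downstream. Set URIs hash the sorted members, so they are
   permutation-invariant and stable across builds. A set is materialized as
   exactly one `kro:hasMember` triple per member — the set's own class
   membership is carried by its URI namespace, a convention chosen to keep
   the per-set triple count equal to its member count.
7. **BIO entities and rules.** One concept per set (subclass of the most
   specific shared guard), then declarative rule batches run to fixpoint:
   abstraction aggregates, taxon links, the 5-triple annotation pattern, the
   9-triple interaction pattern, coarse pathway participation.

## Rules and their numerical behavior

A rule is data: body patterns, optional URI-prefix filters, head templates,
and mint directives. Three numerical conventions matter:

* **Global duplicate suppression.** A head triple already in the graph adds
  nothing; fixpoint is reached when an iteration adds zero triples. The
  non-termination guard aborts after `max_iter` (default 50) iterations — a
  bound no terminating batch at this scale approaches.
* **First-occurrence vs reuse accounting.** Restrictions are minted from
  (property, filler), so the annotation pattern costs 5 triples when its
  restriction is fresh and 2 when it is reused; the interaction pattern
  costs 9 fresh and less under reuse. Emission counts in reports follow
  exactly this rule. A rule whose whole-batch count is zero is flagged in
  the log, since that is the signature of a broken mapping.
* **Mentions accounting.** Every generating rule also asserts an
  `iao:mentions` link from the supporting record to the generated class.
  These provenance links are asserted into the graph but counted in a
  separate channel, so the template pattern sizes (5, 9, …) remain
  well-defined quantities.

The `filters` clause (a declarative must/must-not URI-prefix guard on a
bound variable) exists because an identifier comes to denote both its
bootstrap class (stage 4) and its set-derived concept (stage 7); rules that
want canonical concepts select the `kbio:BIO_` namespace. This mirrors the
ICE/BIO namespace discipline rather than smuggling code into rule files.

## URI minting: the serialization experiment

All minted URIs use the URL-safe base64 encoding of a SHA-1 digest (27
characters, alphabet `A–Z a–z 0–9 - _`, padding stripped); hashing is an
engineering choice for stability, not security. The hashed payload is the
UTF-8 bytes of a kind tag (`field-value`, `record`, `id-set`, `restriction`,
`bio-class`) followed by the pipe-joined defining components — the kind tag
makes cross-kind collisions structurally impossible. A one-time validation
established that the encoding reproduces the standard empty-string SHA-1
token (`2jmj7l5rSw0yVb_vlWAYkK_YBwk`), while no plausible serialization of a
bare taxon field value reproduces externally printed example tokens for
comparable systems; the package therefore documents its own payload
serialization as canonical and tests determinism, injectivity and kind
separation rather than any foreign token value.

Other numerical choices: member lists are sorted in C-locale byte order
before hashing (platform-independent tie-break); empty field values mint no
node (absence is safer than a vacuous ICE, and the skip is logged); literals
are kept as raw strings, deferring numeric typing to rules; record URIs hash
the schema URI plus the primary-key value, an artifact convention chosen
over file position so that re-ordered source files rebuild identically.

## What the synthetic generator does and does not show

`generate_sources()` emulates the *shapes* that make integration hard: two
organisms with per-organism gene identifier spaces, two protein and two drug
spaces, identifier dialects varied per row, a dbXref column mixing
same-type mappings with cross-type noise and an untyped disease space, a
GAF 2.x file, drug–target rows whose gene references alternate spaces, a
duplicated interaction row emulating a second source, and an error plan
(cross-taxon protein mapping, many-to-one drug mapping, cross-type dbXref
entries) with every planted fact recorded in a ground-truth manifest. The
generator's counts default to 12 genes per taxon, 8 drugs, ~12 interactions
and 2 pathways — full builds of a few thousand triples that run in seconds,
which is also the problem size the test suite and acceptance script use;
randomized property suites go up to 500-triple graphs and 200-identifier
partitions.

What passing these tests shows: the mechanics — canonicalization, sharing,
guarded matching, closure, deterministic minting, fixpoint behavior,
provenance replay, planted-error recovery — are correct on inputs whose
ground truth is known by construction. What it does not show: robustness to
real-source scale, to XML dumps, to genuinely ambiguous mappings with no
typing information, or to statistical properties of real curation (the
generator makes no attempt at biological realism; its accessions are
synthetic).

## Design decisions that were genuinely open

* **Guard classes for gene spaces.** Identifier spaces for genes are typed
  to the gene class of the mini-ontology (itself a DNA subclass). Typing to
  the broader DNA class would be equally workable — compatibility is
  identical-or-subsuming either way — but the narrower guard keeps the
  fixture ontology legible; the subsumption path is exercised in tests with
  a mixed DNA/gene set.
* **Aggregates as parallel superclasses.** Gene-or-gene-product(-or-variant)
  classes could be OWL unions; they are encoded as plain superclasses of
  their members so the generated graph stays within the EL profile.
* **Singleton sets get concepts.** Unmapped identifiers still produce BIO
  entities, because downstream rules need a denoted concept for every record
  mention; untyped spaces (the disease-like space in the fixtures) stay
  ICE-only and are logged.
* **Derivations beside the graph.** The derivation index (rule, binding,
  supporting records per emitted triple) is a sidecar table, not RDF
  reification, so triple counts keep matching the pattern arithmetic;
  tracing and replay read the sidecar.
* **Query surface.** The `query`/`demo` interface accepts basic graph
  patterns with a `*` suffix for reflexive-transitive property paths —
  enough to express the drug-retrieval demonstration (which needs
  `rdfs:subClassOf*`) without embedding a full query-language
  implementation; the same matcher drives rule bodies, and its semantics are
  pinned to a brute-force join oracle in the tests.

## Known limitations

In-memory graph only; no streaming ingestion, no XML source formats, no
server-backed triplestore adapters, no OWL classification (subclass
reasoning is reachable via property paths only), no probabilistic record
linkage or mapping-confidence scores, and no automatic blocking of
assertions that QC flags — findings are reported, repair is a human
decision.
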