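# icekb

Ontology-based construction of an integrated biomedical knowledge base from
heterogeneous source files, in R.

## The problem

Anyone who has tried to combine a gene catalog, a protein-annotation file and
a drug–target table knows the failure modes: the same gene written as
`EG513`, `EG:513` or bare `513`; cross-reference columns that silently mix
genes, proteins, drugs and diseases; one biological entity carrying a
different identifier in every source; and — once the data are merged — no way
to say *why* the merged resource asserts what it asserts.

`icekb` addresses these problems by building an RDF knowledge base in two
strictly separated halves:

* the **ICE side** (information content entities): every database, schema,
  record, field, field value and identifier is represented explicitly as an
  informational artifact, exactly as it appeared in the source;
* the **BIO side** (biomedical concepts): genes, proteins, drugs, processes
  and interactions, grounded in OBO-style ontology classes and generated
  *only* by declarative forward-chaining rules reading the ICE side.

The only links crossing the demarcation are the aboutness relations
`iao:denotes`, `iao:mentions` and `iao:is_about`, which is what makes every
biomedical assertion traceable back to the records and rules that produced
it.

## The core machinery

* **Deterministic skolemization.** Every generated node — field value,
  record, identifier set, OWL restriction, dynamically generated class — gets
  a URI built from the URL-safe base64 encoding of a SHA-1 hash of the values
  that functionally define it (`sha1_b64url()`, `mint_*()`). No blank nodes,
  no lookup tables: identical inputs re-mint identical URIs in every build,
  shared structure (field values, restrictions) is stored once, and two
  sources reporting the same fact necessarily produce the same triples.
* **Identifier canonicalization.** Declarative dialect rules map every
  lexical variant of an identifier to one canonical ICE URI
  (`canonicalize_identifier()`); unknown dialects quarantine the record and
  the build continues.
* **Identity resolution.** Bootstrap typing asserts what kind of thing each
  identifier space denotes (`X kiao:denotesSubClassOf Z`, a macro for
  `X iao:denotes Y . Y rdfs:subClassOf Z`). Type-guarded rules then extract
  `skos:exactMatch` links only between identifiers denoting the same kind of
  entity — a gene is never "exactly matched" to its protein or to a drug in a
  dbXref column. The links are closed into disjoint identifier sets with
  union–find, each set materialized with one `kro:hasMember` triple per
  member and given a single BIO concept that every member denotes.
* **Forward-chaining rules.** Declarative YAML rules (body = triple patterns,
  head = template with deterministic mint directives) are run in batches to
  fixpoint. The shipped rules generate the all-some annotation pattern (a new
  process subclass with a `has_participant` restriction — 5 triples per fresh
  binding), the drug–gene interaction pattern (two participant restrictions
  plus an interaction subclass — 9 triples at first occurrence, fewer when
  restrictions are reused), sequence-abstraction aggregates
  (gene-or-gene-product, gene-or-gene-product-or-variant, encoded as parallel
  superclasses to stay EL-friendly), and coarse-grained pathway
  participation.
* **Provenance and QC.** Every rule emission is recorded in a derivation
  index (rule, binding, supporting records) and can be replayed;
  `run_qc()` hunts for assertions that should not exist — an entity in two
  disjoint taxa, two same-source identifiers in one set, one external
  identifier claimed by several records.

A deterministic fixture generator (`generate_sources()`) emulates the source
shapes — a gene catalog with mixed-type dbXref, mapping tables, a GAF 2.x
annotation file, drug–target and pathway tables, with identifier dialects
deliberately varied and errors planted on request — and emits a ground-truth
manifest so every check is non-circular.

## Worked example

```r
library(icekb)

src <- tempfile()
generate_sources(fixture_spec(seed = 101), src)  # synthetic sources + manifest
res <- kb_build(src)                             # full staged build
res$report
#>                   stage new_triples total
#>                  <char>       <int> <int>
#> 1:             ontology         108   108
#> 2:          ice-records        1984  2092
#> 3:           owl-to-ice          15  2107
#> 4:         entity-types         339  2446
#> 5:        exact-matches          57  2503
#> 6: id-sets-and-entities         282  2785
#> 7:            bio-rules         563  3348
```

The stages mirror the construction flow: ontologies load first; source files
are RDFized into ICE records (the 1984 triples above, with shared field
values already deduplicated); ontology concepts get identifier ICEs;
bootstrap typing and macro expansion run; exact matches are extracted under
type guards (57 triples — the filtered cross-type candidates are only
logged); union–find produces the identifier sets and their BIO entities; and
the rule batches generate the biomedical representations.

Querying in purely biomedical terms — *which drugs hit gene products that
participate in oxidative phosphorylation and localize to mitochondria?* —
walks subclass property paths through the generated classes:

```r
demo_query(res$graph)
#>                                                     drug
#> 1: http://icekb.org/kbio/BIO_P-cBn0airxIwa-li-jWwW1PrL1w
#> 2: http://icekb.org/kbio/BIO_UR-h2cUVHpwzyYoMc2zzrp8IqRM
#> 3: http://icekb.org/kbio/BIO__fxZaA9R0pMPL0RUVjfODy8N7Is
#>                                                                             ids
#> 1: http://icekb.org/kiao/cid/CID_5001_ICE http://icekb.org/kiao/db/DB_1001_ICE
#> 2: http://icekb.org/kiao/cid/CID_5002_ICE http://icekb.org/kiao/db/DB_1002_ICE
#> 3: http://icekb.org/kiao/cid/CID_5003_ICE http://icekb.org/kiao/db/DB_1003_ICE
```

Each answer is a drug concept with the identifier ICEs that denote it; on the
fixture these are exactly the planted answer drugs. Provenance runs the other
way: `trace_concept()` returns the identifiers and records behind any
concept, and `trace_triple()` returns the (rule, binding, records)
derivations of any generated triple.

A thin command-line wrapper is installed as `exec/icekb`
(`icekb fixtures | build | merge-ids | qc | demo | trace | query`).

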