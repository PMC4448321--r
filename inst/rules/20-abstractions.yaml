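# Sequence-abstraction layers: per gene class, aggregate gene-or-gene-product
# and gene-or-gene-product-or-variant classes encoded as plain superclasses
# (EL-compatible parallel-superclass encoding, no owl:unionOf), plus the
# indirect-template link from coding gene to protein. Aggregate URIs are
# minted from the base gene class, so every rule needing the aggregate
# re-mints the identical URI.
batch: abstractions
rules:
  - name: gene-aggregates
    body:
      - ["?gene", "rdfs:subClassOf", "obo:SO_0000704"]
    filters:
      - {var: "?gene", prefix: "kbio:BIO_"}
    head:
      - ["?gene", "rdfs:subClassOf", "?gorgp"]
      - ["?gene", "rdfs:subClassOf", "?gorgpv"]
    mint:
      "?gorgp": {kind: bio-class, subtag: aggregate, components: ["GorGP", "?gene"], prefix: "GorGP_BIO_"}
      "?gorgpv": {kind: bio-class, subtag: aggregate, components: ["GorGPorV", "?gene"], prefix: "GorGPorV_BIO_"}
  - name: gene-product-links
    body:
      - ["?r", "kiao:has_template", "kiao:schema/gene_catalog"]
      - ["?r", "obo:has_part", "?gfv"]
      - ["?gfv", "kiao:has_template", "kiao:schema/gene_catalog/gene_id"]
      - ["?gfv", "kiao:has_field_value", "?gid"]
      - ["?r", "obo:has_part", "?pfv"]
      - ["?pfv", "kiao:has_template", "kiao:schema/gene_catalog/protein_id"]
      - ["?pfv", "kiao:has_field_value", "?pid"]
      - ["?gid", "iao:denotes", "?gene"]
      - ["?pid", "iao:denotes", "?protein"]
    filters:
      - {var: "?gene", prefix: "kbio:BIO_"}
      - {var: "?protein", prefix: "kbio:BIO_"}
    head:
      - ["?protein", "kro:has_indirect_template", "?gene"]
      - ["?protein", "rdfs:subClassOf", "?gorgp"]
      - ["?protein", "rdfs:subClassOf", "?gorgpv"]
    mint:
      "?gorgp": {kind: bio-class, subtag: aggregate, components: ["GorGP", "?gene"], prefix: "GorGP_BIO_"}
      "?gorgpv": {kind: bio-class, subtag: aggregate, components: ["GorGPorV", "?gene"], prefix: "GorGPorV_BIO_"}
    mentions: {record: "?r", concept: "?gorgpv"}
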