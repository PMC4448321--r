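# Default build configuration for the shipped fixture layout.
sources:
  - {file: gene_catalog.tsv, schema: gene_catalog}
  - {file: protein_mapping.tsv, schema: protein_mapping}
  - {file: drug_mapping.tsv, schema: drug_mapping}
  - {file: drug_targets.csv, schema: drug_targets}
  - {file: pathway.tsv, schema: pathway}
  - {file: goa.gaf, schema: goa}
ontologies: [ontology.ttl]
ontology_ice_spaces: [GO, NCBITaxon]
# bootstrap entity typing: identifier space -> ontology class its
# identifiers' denoted concepts will subclass
type_assertions:
  EG: obo:SO_0000704
  HGNC: obo:SO_0000704
  MGI: obo:SO_0000704
  UP: obo:PR_000000001
  IPI: obo:PR_000000001
  DB: obo:CHEBI_23888
  CID: obo:CHEBI_23888
  PW: obo:PW_0000001
# type-guarded exact-match extraction: record schema + left/right fields
mapping_specs:
  - {schema: gene_catalog, left: gene_id, right: dbxref}
  - {schema: protein_mapping, left: up_id, right: ipi_id}
  - {schema: drug_mapping, left: db_id, right: cid_id}
# BIO rule batches, in stage order
rule_batches:
  - 20-abstractions.yaml
  - 25-taxon.yaml
  - 30-goa.yaml
  - 40-interactions.yaml
  - 50-pathways.yaml
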