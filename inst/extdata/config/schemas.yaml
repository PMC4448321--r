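# Source schema templates. `space` designates the identifier space a field is
# declared to contain (bare locals allowed there); `mixed: true` marks
# cross-reference fields holding prefixed identifiers from any space;
# `multi` gives the separator of multi-valued fields.
schemas:
  gene_catalog:
    format: delimited
    delimiter: "\t"
    primary_key: gene_id
    fields:
      - {name: gene_id, space: EG}
      - {name: symbol}
      - {name: taxon_id, space: NCBITaxon}
      - {name: protein_id, space: UP}
      - {name: dbxref, mixed: true, multi: ";"}
      - {name: description}
  protein_mapping:
    format: delimited
    delimiter: "\t"
    primary_key: up_id
    fields:
      - {name: up_id, space: UP}
      - {name: ipi_id, space: IPI}
  drug_mapping:
    format: delimited
    delimiter: "\t"
    primary_key: db_id
    fields:
      - {name: db_id, space: DB}
      - {name: cid_id, space: CID}
  drug_targets:
    format: delimited
    delimiter: ","
    primary_key: row_id
    fields:
      - {name: row_id}
      - {name: drug_id, space: DB}
      - {name: drug_name}
      - {name: target_id, mixed: true}
      - {name: action}
  pathway:
    format: delimited
    delimiter: "\t"
    primary_key: pathway_id
    fields:
      - {name: pathway_id, space: PW}
      - {name: pathway_name}
      - {name: member_ids, space: UP, multi: ";"}
  goa:
    format: gaf
    primary_key: row_id
    fields:
      - {name: row_id}
      - {name: db}
      - {name: object_id, space: UP}
      - {name: go_id, space: GO}
      - {name: evidence}
      - {name: aspect}
      - {name: taxon_id, space: NCBITaxon}
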