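# Species links: BIO entities carry a kro:in_taxon link derived from the
# taxon field of the source record that mentions them; needed for the
# disjoint-taxa quality-control check.
batch: taxon
rules:
  - name: gene-taxon
    body:
      - ["?r", "kiao:has_template", "kiao:schema/gene_catalog"]
      - ["?r", "obo:has_part", "?gfv"]
      - ["?gfv", "kiao:has_template", "kiao:schema/gene_catalog/gene_id"]
      - ["?gfv", "kiao:has_field_value", "?gid"]
      - ["?r", "obo:has_part", "?tfv"]
      - ["?tfv", "kiao:has_template", "kiao:schema/gene_catalog/taxon_id"]
      - ["?tfv", "kiao:has_field_value", "?tid"]
      - ["?gid", "iao:denotes", "?gene"]
      - ["?tid", "iao:denotes", "?taxon"]
    filters:
      - {var: "?gene", prefix: "kbio:BIO_"}
      - {var: "?taxon", prefix: "obo:NCBITaxon_"}
    head:
      - ["?gene", "kro:in_taxon", "?taxon"]
  - name: protein-taxon
    body:
      - ["?r", "kiao:has_template", "kiao:schema/goa"]
      - ["?r", "obo:has_part", "?pfv"]
      - ["?pfv", "kiao:has_template", "kiao:schema/goa/object_id"]
      - ["?pfv", "kiao:has_field_value", "?pid"]
      - ["?r", "obo:has_part", "?tfv"]
      - ["?tfv", "kiao:has_template", "kiao:schema/goa/taxon_id"]
      - ["?tfv", "kiao:has_field_value", "?tid"]
      - ["?pid", "iao:denotes", "?protein"]
      - ["?tid", "iao:denotes", "?taxon"]
    filters:
      - {var: "?protein", prefix: "kbio:BIO_"}
      - {var: "?taxon", prefix: "obo:NCBITaxon_"}
    head:
      - ["?protein", "kro:in_taxon", "?taxon"]
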