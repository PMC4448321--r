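# Drug-gene interaction rule: nine triples at first occurrence -- two
# all-some participant restrictions (3 triples each: the drug, and the gene's
# gene-or-gene-product-or-variant aggregate, since curation rarely says
# whether the drug binds the gene or one of its products) and an interaction
# subclass with 3 subclass triples (parent interaction class + both
# restrictions). All URIs are pure functions of the participants, so a second
# source reporting the same interaction re-mints the identical triples.
batch: interactions
rules:
  - name: drug-gene-interaction
    body:
      - ["?r", "kiao:has_template", "kiao:schema/drug_targets"]
      - ["?r", "obo:has_part", "?dfv"]
      - ["?dfv", "kiao:has_template", "kiao:schema/drug_targets/drug_id"]
      - ["?dfv", "kiao:has_field_value", "?did"]
      - ["?r", "obo:has_part", "?tfv"]
      - ["?tfv", "kiao:has_template", "kiao:schema/drug_targets/target_id"]
      - ["?tfv", "kiao:has_field_value", "?tid"]
      - ["?did", "iao:denotes", "?drug"]
      - ["?tid", "iao:denotes", "?gene"]
    filters:
      - {var: "?drug", prefix: "kbio:BIO_"}
      - {var: "?gene", prefix: "kbio:BIO_"}
    head:
      - ["?rg", "rdf:type", "owl:Restriction"]
      - ["?rg", "owl:onProperty", "obo:RO_0000057"]
      - ["?rg", "owl:someValuesFrom", "?gorgpv"]
      - ["?rd", "rdf:type", "owl:Restriction"]
      - ["?rd", "owl:onProperty", "obo:RO_0000057"]
      - ["?rd", "owl:someValuesFrom", "?drug"]
      - ["?i", "rdfs:subClassOf", "obo:MI_0000"]
      - ["?i", "rdfs:subClassOf", "?rg"]
      - ["?i", "rdfs:subClassOf", "?rd"]
    mint:
      "?gorgpv": {kind: bio-class, subtag: aggregate, components: ["GorGPorV", "?gene"], prefix: "GorGPorV_BIO_"}
      "?rg": {kind: restriction, components: ["obo:RO_0000057", "?gorgpv"]}
      "?rd": {kind: restriction, components: ["obo:RO_0000057", "?drug"]}
      "?i": {kind: bio-class, subtag: interaction, components: ["obo:MI_0000", "?rd", "?rg"], prefix: "I_"}
    mentions: {record: "?r", concept: "?i"}
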