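# Coarse-grained pathway rule: a pathway record with member proteins is
# modeled at high granularity as a pathway subclass that has each protein as
# a participant (one new pathway subclass per pathway, one reusable
# participant restriction per protein). Finer-grained rules over the same
# records can coexist without conflict.
batch: pathways
rules:
  - name: pathway-participants
    body:
      - ["?r", "kiao:has_template", "kiao:schema/pathway"]
      - ["?r", "obo:has_part", "?wfv"]
      - ["?wfv", "kiao:has_template", "kiao:schema/pathway/pathway_id"]
      - ["?wfv", "kiao:has_field_value", "?wid"]
      - ["?r", "obo:has_part", "?mfv"]
      - ["?mfv", "kiao:has_template", "kiao:schema/pathway/member_ids"]
      - ["?mfv", "kiao:has_field_value", "?mid"]
      - ["?wid", "iao:denotes", "?pw"]
      - ["?mid", "iao:denotes", "?protein"]
    filters:
      - {var: "?pw", prefix: "kbio:BIO_"}
      - {var: "?protein", prefix: "kbio:BIO_"}
    head:
      - ["?npw", "rdfs:subClassOf", "?pw"]
      - ["?rp", "rdf:type", "owl:Restriction"]
      - ["?rp", "owl:onProperty", "obo:RO_0000057"]
      - ["?rp", "owl:someValuesFrom", "?protein"]
      - ["?npw", "rdfs:subClassOf", "?rp"]
    mint:
      "?rp": {kind: restriction, components: ["obo:RO_0000057", "?protein"]}
      "?npw": {kind: bio-class, subtag: pathway, components: ["?pw"], prefix: "PWY_"}
    mentions: {record: "?r", concept: "?npw"}
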