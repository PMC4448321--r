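# GO-annotation rules. A process (aspect P) annotation generates a new
# process class, formally a subclass of the annotated GO process with an
# all-some restriction that the annotated protein participates: exactly the
# 5-triple template (3 of which define the restriction, reused graph-wide).
# A component (aspect C) annotation generates a localization subclass with a
# participant restriction on the protein and a location restriction on the
# component.
batch: goa
rules:
  - name: goa-process
    body:
      - ["?r", "kiao:has_template", "kiao:schema/goa"]
      - ["?r", "obo:has_part", "?afv"]
      - ["?afv", "kiao:has_template", "kiao:schema/goa/aspect"]
      - ["?afv", "kiao:has_field_value", "\"P\""]
      - ["?r", "obo:has_part", "?pfv"]
      - ["?pfv", "kiao:has_template", "kiao:schema/goa/object_id"]
      - ["?pfv", "kiao:has_field_value", "?pid"]
      - ["?r", "obo:has_part", "?gfv"]
      - ["?gfv", "kiao:has_template", "kiao:schema/goa/go_id"]
      - ["?gfv", "kiao:has_field_value", "?gid"]
      - ["?pid", "iao:denotes", "?protein"]
      - ["?gid", "iao:denotes", "?goProcess"]
    filters:
      - {var: "?protein", prefix: "kbio:BIO_"}
      - {var: "?goProcess", prefix: "obo:GO_"}
    head:
      - ["?newProcess", "rdfs:subClassOf", "?goProcess"]
      - ["?participant", "rdf:type", "owl:Restriction"]
      - ["?participant", "owl:onProperty", "obo:RO_0000057"]
      - ["?participant", "owl:someValuesFrom", "?protein"]
      - ["?newProcess", "rdfs:subClassOf", "?participant"]
    mint:
      "?participant": {kind: restriction, components: ["obo:RO_0000057", "?protein"]}
      "?newProcess": {kind: bio-class, subtag: goa-process, components: ["?goProcess", "?participant"], prefix: "GOA_"}
    mentions: {record: "?r", concept: "?newProcess"}
  - name: goa-localization
    body:
      - ["?r", "kiao:has_template", "kiao:schema/goa"]
      - ["?r", "obo:has_part", "?afv"]
      - ["?afv", "kiao:has_template", "kiao:schema/goa/aspect"]
      - ["?afv", "kiao:has_field_value", "\"C\""]
      - ["?r", "obo:has_part", "?pfv"]
      - ["?pfv", "kiao:has_template", "kiao:schema/goa/object_id"]
      - ["?pfv", "kiao:has_field_value", "?pid"]
      - ["?r", "obo:has_part", "?gfv"]
      - ["?gfv", "kiao:has_template", "kiao:schema/goa/go_id"]
      - ["?gfv", "kiao:has_field_value", "?gid"]
      - ["?pid", "iao:denotes", "?protein"]
      - ["?gid", "iao:denotes", "?component"]
    filters:
      - {var: "?protein", prefix: "kbio:BIO_"}
      - {var: "?component", prefix: "obo:GO_"}
    head:
      - ["?newLoc", "rdfs:subClassOf", "obo:GO_0051179"]
      - ["?participant", "rdf:type", "owl:Restriction"]
      - ["?participant", "owl:onProperty", "obo:RO_0000057"]
      - ["?participant", "owl:someValuesFrom", "?protein"]
      - ["?newLoc", "rdfs:subClassOf", "?participant"]
      - ["?location", "rdf:type", "owl:Restriction"]
      - ["?location", "owl:onProperty", "obo:RO_0001025"]
      - ["?location", "owl:someValuesFrom", "?component"]
      - ["?newLoc", "rdfs:subClassOf", "?location"]
    mint:
      "?participant": {kind: restriction, components: ["obo:RO_0000057", "?protein"]}
      "?location": {kind: restriction, components: ["obo:RO_0001025", "?component"]}
      "?newLoc": {kind: bio-class, subtag: localization, components: ["?component", "?participant"], prefix: "LOC_"}
    mentions: {record: "?r", concept: "?newLoc"}
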