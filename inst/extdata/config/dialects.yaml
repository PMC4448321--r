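# Identifier dialect rules. One entry per identifier space. `patterns` are
# full-string regexes with exactly one capture group (the local part),
# accepted in any field; `bare_pattern` is accepted only in fields designated
# to contain identifiers from that space. Prefixed patterns across spaces are
# mutually non-ambiguous by construction.
spaces:
  EG:
    label: gene identifiers, NCBI-Gene-like space
    uri_dir: eg
    patterns: ["^EG[:_ ]?([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
  HGNC:
    label: human gene identifiers, HGNC-like space
    uri_dir: hgnc
    patterns: ["^HGNC[:_]?([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
  MGI:
    label: mouse gene identifiers, MGI-like space
    uri_dir: mgi
    patterns: ["^MGI[:_]?([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
  UP:
    label: protein accessions, UniProt-like space
    uri_dir: up
    patterns: ["^(?:UniProtKB|UniProt|UP)[:_]?([A-Z][0-9A-Z]{5})$"]
    bare_pattern: "^([A-Z][0-9A-Z]{5})$"
  IPI:
    label: protein accessions, secondary (IPI-like) space
    uri_dir: ipi
    patterns: ["^IPI[:_]?([0-9]{6,})$"]
    bare_pattern: "^([0-9]{6,})$"
  DB:
    label: drug identifiers, DrugBank-like space
    uri_dir: db
    patterns: ["^DB[:_]?([0-9]{4,})$"]
    bare_pattern: "^([0-9]{4,})$"
  CID:
    label: drug identifiers, PubChem-CID-like space
    uri_dir: cid
    patterns: ["^CID[:_]?([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
  GO:
    label: Gene Ontology class identifiers
    uri_dir: go
    patterns: ["^GO[:_]?([0-9]{7})$"]
    bare_pattern: "^([0-9]{7})$"
  PW:
    label: pathway identifiers
    uri_dir: pw
    patterns: ["^PW[:_]?([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
  NCBITaxon:
    label: organism taxon identifiers
    uri_dir: ncbitaxon
    patterns: ["^(?:NCBITaxon|taxon)[:_]([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
  MIM:
    label: disease identifiers, OMIM-like space (no entity-type assertion)
    uri_dir: mim
    patterns: ["^MIM[:_]?([0-9]+)$"]
    bare_pattern: "^([0-9]+)$"
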