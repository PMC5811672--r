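{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cellmapr protein database",
  "description": "A protein database is a single JSON array of protein documents. Localization order is significant: the first entry is the protein's primary localization and is where the PPI viewer places it by default. An absent interaction score means an unscored (unlabeled) edge and is distinct from a score of zero. Timestamps are carried verbatim and never interpreted.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["uniprot_id"],
    "properties": {
      "uniprot_id": {"type": "string", "minLength": 1, "description": "UniProt accession; unique within the database"},
      "gene_name": {"type": "string", "description": "primary gene name"},
      "protein_name": {"type": "string", "description": "primary protein name"},
      "interactions": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["partner_id"],
          "properties": {
            "partner_id": {"type": "string", "minLength": 1},
            "score": {"type": "number", "minimum": 0, "maximum": 1, "description": "experimental reliability of the interaction; optional"},
            "source": {"type": "string"}
          }
        }
      },
      "localizations": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["compartment"],
          "properties": {
            "compartment": {"type": "string", "minLength": 1, "description": "compartment name, matched against ROI names case-insensitively after trimming"},
            "source": {"type": "string"}
          }
        }
      },
      "created_at": {"type": "string", "format": "date-time"},
      "updated_at": {"type": "string", "format": "date-time"}
    }
  }
}
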