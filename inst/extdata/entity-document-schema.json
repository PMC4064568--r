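{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pathwaycv entity document",
  "description": "Entity and reaction document consumed by the CV naming tools. Coordinates are 1-based integers; the string '?' denotes an unknown coordinate. Top-level entities carry local ids; parts and participants may reference them as {\"ref\": id}.",
  "type": "object",
  "required": ["version", "entities"],
  "properties": {
    "version": {"const": "1.0"},
    "entities": {
      "type": "array",
      "items": {
        "allOf": [{"$ref": "#/$defs/entity"}],
        "properties": {"id": {"type": "string"}}
      }
    },
    "reactions": {"type": "array", "items": {"$ref": "#/$defs/reaction"}}
  },
  "$defs": {
    "coordinate": {"oneOf": [{"type": "integer", "minimum": 1}, {"const": "?"}]},
    "entityOrRef": {
      "oneOf": [
        {"$ref": "#/$defs/entity"},
        {"type": "object", "required": ["ref"], "properties": {"ref": {"type": "string"}}}
      ]
    },
    "entity": {
      "type": "object",
      "required": ["type"],
      "properties": {
        "type": {"enum": ["peptide", "molecule", "complex", "defined_set", "candidate_set"]},
        "name": {"type": "string", "description": "previous free-text name, retained as an alias"},
        "gene_symbol": {"type": "string"},
        "start": {"$ref": "#/$defs/coordinate"},
        "end": {"$ref": "#/$defs/coordinate"},
        "chain_start": {"oneOf": [{"$ref": "#/$defs/coordinate"}, {"type": "null"}]},
        "chain_end": {"oneOf": [{"$ref": "#/$defs/coordinate"}, {"type": "null"}]},
        "chain_count": {"type": "integer", "minimum": 0},
        "ptms": {"type": "array", "items": {"$ref": "#/$defs/ptm"}},
        "isoform_variant": {"type": "integer", "minimum": 1},
        "active": {"type": "boolean"},
        "disease_mutation": {"type": "boolean"},
        "cross_link": {"type": "boolean"},
        "hla": {"type": "boolean"},
        "reference_name": {"type": "string"},
        "chebi_id": {"type": ["string", "null"]},
        "functional_label": {"type": ["string", "null"]},
        "parts": {"type": "array", "minItems": 1, "items": {"$ref": "#/$defs/part"}}
      }
    },
    "ptm": {
      "type": "object",
      "required": ["psimod_id"],
      "properties": {
        "psimod_id": {"type": "string"},
        "subtype": {"enum": ["S", "T", "Y"]},
        "coordinate": {"$ref": "#/$defs/coordinate"},
        "multiplicity": {"type": "integer", "minimum": 1}
      }
    },
    "part": {
      "type": "object",
      "required": ["entity"],
      "properties": {
        "entity": {"$ref": "#/$defs/entityOrRef"},
        "stoichiometry": {"type": "integer", "minimum": 1},
        "candidate": {"type": "boolean"}
      }
    },
    "participant": {
      "type": "object",
      "required": ["entity"],
      "properties": {
        "entity": {"$ref": "#/$defs/entityOrRef"},
        "compartment": {"type": ["string", "null"]},
        "count": {"type": "integer", "minimum": 1},
        "cell_type": {"type": ["string", "null"]}
      }
    },
    "reaction": {
      "type": "object",
      "properties": {
        "name": {"type": "string"},
        "inputs": {"type": "array", "items": {"$ref": "#/$defs/participant"}},
        "outputs": {"type": "array", "items": {"$ref": "#/$defs/participant"}},
        "catalyst": {"$ref": "#/$defs/entityOrRef"},
        "catalyst_gomf": {"type": ["string", "null"]},
        "regulator": {
          "type": "object",
          "required": ["entity"],
          "properties": {
            "entity": {"$ref": "#/$defs/entityOrRef"},
            "sign": {"enum": ["positive", "negative"]}
          }
        },
        "explicit_class": {"enum": ["polymerization", "depolymerization"]},
        "transferred": {"$ref": "#/$defs/entityOrRef"},
        "membrane": {"type": ["string", "null"]}
      }
    }
  }
}
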