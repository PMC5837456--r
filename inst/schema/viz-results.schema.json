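{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phenome-scan visualization results",
  "description": "Hierarchical category tree with tested variables as leaves; consumed by interactive result browsers.",
  "$defs": {
    "variable": {
      "type": "object",
      "required": ["name", "field_id", "p", "data_type", "below_threshold"],
      "properties": {
        "name": {"type": "string"},
        "field_id": {"type": "integer"},
        "p": {"type": ["number", "null"]},
        "estimate": {"type": ["number", "null"]},
        "data_type": {"enum": ["CONTINUOUS", "ORDERED", "UNORDERED", "BINARY"]},
        "below_threshold": {"type": "boolean"}
      }
    },
    "category": {
      "type": "object",
      "required": ["category_id", "title", "children", "variables"],
      "properties": {
        "category_id": {"type": "integer"},
        "title": {"type": "string"},
        "children": {"type": "array", "items": {"$ref": "#/$defs/category"}},
        "variables": {"type": "array", "items": {"$ref": "#/$defs/variable"}}
      }
    }
  },
  "allOf": [{"$ref": "#/$defs/category"}],
  "type": "object",
  "required": ["scan"],
  "properties": {
    "scan": {
      "type": "object",
      "required": ["m_tests", "alpha", "threshold"],
      "properties": {
        "m_tests": {"type": "integer"},
        "alpha": {"type": "number"},
        "threshold": {"type": "number"}
      }
    }
  }
}
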