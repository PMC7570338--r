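{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "molcolor molecular graph",
  "description": "JSON dialect emitted by mol_to_json() and accepted by mol_from_json(). Atom indices are 0-based; bond endpoints reference atom indices.",
  "type": "object",
  "required": ["atoms", "bonds"],
  "properties": {
    "source_id": {"type": "string"},
    "atoms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["index", "element"],
        "properties": {
          "index": {"type": "integer", "minimum": 0},
          "element": {"type": "string", "minLength": 1},
          "charge": {"type": "integer"},
          "stereo_parity": {"type": "integer"},
          "mass_delta": {"type": "integer"},
          "x": {"type": "number"},
          "y": {"type": "number"},
          "z": {"type": "number"},
          "is_aromatic": {"type": "boolean"}
        }
      }
    },
    "bonds": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["a", "b", "order"],
        "properties": {
          "a": {"type": "integer", "minimum": 0},
          "b": {"type": "integer", "minimum": 0},
          "order": {"type": "integer", "enum": [1, 2, 3, 4]},
          "wedge": {"type": "integer"},
          "cis_trans": {"type": "string", "enum": ["none", "cis", "trans"]}
        }
      }
    }
  }
}
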