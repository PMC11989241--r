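{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Mood-state decomposition of a windowed Hurst density",
  "type": "object",
  "required": ["inflection_points", "states", "observable_state", "tail_mass"],
  "properties": {
    "inflection_points": {
      "type": "array", "minItems": 2, "items": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "states": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "required": ["interval", "probability", "label"],
        "properties": {
          "interval": {"type": "array", "minItems": 2, "maxItems": 2, "items": {"type": "number"}},
          "probability": {"type": "number", "minimum": 0, "maximum": 1},
          "label": {"enum": ["mania", "stable", "depression"]},
          "extremum": {"enum": ["meta_stable", "stable", "transition"]}
        }
      }
    },
    "observable_state": {"type": "integer", "minimum": 1},
    "tail_mass": {"type": "number", "minimum": 0, "maximum": 1}
  }
}
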