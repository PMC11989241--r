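{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Scenario-library extrapolation of a windowed Hurst trajectory",
  "type": "object",
  "required": ["selected_h", "distance", "extended_trajectory", "trend"],
  "properties": {
    "selected_h": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "selected_id": {"type": "integer", "minimum": 1},
    "distance": {"type": "number", "minimum": 0},
    "p": {"type": "number", "minimum": 1},
    "observed": {"type": "array", "items": {"type": "number"}},
    "extended_trajectory": {"type": "array", "minItems": 2, "items": {"type": "number"}},
    "trend": {"type": "array"}
  }
}
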