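{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "lamadapt LAM set",
  "type": "object",
  "required": ["format_version", "domain", "u_global", "oracle_id", "lams"],
  "properties": {
    "format_version": {"const": 1},
    "domain": {
      "type": "object",
      "required": ["lower", "upper", "periodic", "half_spacing"],
      "properties": {
        "names": {"type": "array", "items": {"type": "string"}},
        "lower": {"type": "array", "items": {"type": "number"}},
        "upper": {"type": "array", "items": {"type": "number"}},
        "periodic": {"type": "array", "items": {"type": "boolean"}},
        "half_spacing": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}}
      }
    },
    "u_global": {"type": "number"},
    "oracle_id": {"type": "string"},
    "build_params": {"type": "object"},
    "log": {"type": "array", "items": {"type": "string"}},
    "lams": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["theta_ref", "e_ref", "b", "a", "beta_ref", "c"],
        "properties": {
          "theta_ref": {"type": "array", "items": {"type": "number"}},
          "e_ref": {"type": "number", "minimum": -1e-6},
          "b": {"type": "array", "items": {"type": "number"}},
          "a": {
            "type": "array", "items": {"type": "number"},
            "description": "row-major symmetric second-derivative matrix, kJ/mol/deg^2"
          },
          "beta_ref": {"type": "array", "items": {"type": "number"}},
          "c": {
            "type": "array", "items": {"type": "number"},
            "description": "row-major dependent-DOF sensitivity matrix, rows = dependent DOFs"
          },
          "n_dep": {"type": "integer", "minimum": 0},
          "payload": {"type": "object"}
        },
        "additionalProperties": true
      }
    }
  }
}
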