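{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "lamadapt synthetic torsional potential",
  "type": "object",
  "required": ["format_version", "id", "n_indep", "n_dep"],
  "properties": {
    "format_version": {"const": 1},
    "id": {"type": "string"},
    "n_indep": {"type": "integer", "minimum": 1},
    "n_dep": {"type": "integer", "minimum": 0},
    "const": {"type": "number"},
    "fourier": {
      "type": "object",
      "description": "column-wise terms V*(1 - cos(mult*theta_dim + phase)), phases in degrees",
      "properties": {
        "dim": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "mult": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "barrier": {"type": "array", "items": {"type": "number"}},
        "phase": {"type": "array", "items": {"type": "number"}}
      }
    },
    "coupling": {
      "type": "object",
      "description": "column-wise terms amp*cos(mult_i*theta_i + phase_i)*cos(mult_j*theta_j + phase_j)",
      "properties": {
        "dim_i": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "dim_j": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "amp": {"type": "array", "items": {"type": "number"}},
        "mult_i": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "mult_j": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "phase_i": {"type": "array", "items": {"type": "number"}},
        "phase_j": {"type": "array", "items": {"type": "number"}}
      }
    },
    "dep": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["beta0", "terms"],
        "properties": {
          "beta0": {"type": "number"},
          "terms": {
            "type": "object",
            "description": "column-wise sinusoidal target terms; mult 0 denotes a linear term slope*theta_dim",
            "properties": {
              "dim": {"type": "array", "items": {"type": "integer", "minimum": 1}},
              "slope": {"type": "array", "items": {"type": "number"}},
              "mult": {"type": "array", "items": {"type": "integer", "minimum": 0}},
              "phase": {"type": "array", "items": {"type": "number"}}
            }
          }
        }
      }
    },
    "kappa": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}},
    "quadratic": {
      "type": ["object", "null"],
      "properties": {
        "theta0": {"type": "array", "items": {"type": "number"}},
        "curvature": {"type": "array", "items": {"type": "number", "minimum": 0}}
      }
    }
  }
}
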