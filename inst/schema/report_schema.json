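{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "petitv comparison report",
  "type": "object",
  "required": ["per_lesion", "summary", "tests", "exceptions"],
  "properties": {
    "per_lesion": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["lesion", "ptv_cc", "ptvg_cc", "bitv_cc", "btv_cc",
                     "ptv_ptvg_pct", "bitv_btv_pct"],
        "properties": {
          "lesion": {"type": "integer"},
          "ptv_cc": {"type": "number", "minimum": 0},
          "ptvg_cc": {"type": "number", "minimum": 0},
          "bitv_cc": {"type": "number", "minimum": 0},
          "btv_cc": {"type": "number", "minimum": 0},
          "ctv_cc": {"type": "number", "minimum": 0},
          "ptv_ptvg_pct": {"type": "integer"},
          "bitv_btv_pct": {"type": "integer"}
        }
      }
    },
    "summary": {
      "type": "object",
      "required": ["columns", "ratio_of_means_pct"],
      "properties": {
        "columns": {"type": "array"},
        "ratio_of_means_pct": {
          "type": "object",
          "required": ["ptv_ptvg", "bitv_btv"],
          "properties": {
            "ptv_ptvg": {"type": "number"},
            "bitv_btv": {"type": "number"}
          }
        }
      }
    },
    "tests": {
      "type": "object",
      "required": ["ptv_vs_ptvg", "bitv_vs_btv"],
      "additionalProperties": {
        "type": "object",
        "required": ["W", "p", "n_pairs", "n_nonzero", "method"],
        "properties": {
          "W": {"type": "number", "minimum": 0},
          "p": {"type": "number", "minimum": 0, "maximum": 1},
          "n_pairs": {"type": "integer", "minimum": 1},
          "n_nonzero": {"type": "integer", "minimum": 0},
          "method": {"enum": ["exact", "approximate"]},
          "degenerate": {"type": "boolean"}
        }
      }
    },
    "exceptions": {"type": "integer", "minimum": 0}
  }
}
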