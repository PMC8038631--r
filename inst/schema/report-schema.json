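{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "muacjglm pipeline report",
  "type": "object",
  "required": ["descriptives", "correlations", "screen", "glm", "joint",
               "comparison", "diagnostics"],
  "properties": {
    "descriptives": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "minimum", "maximum", "mean", "median",
                     "sd", "n"]
      }
    },
    "correlations": {
      "type": "object",
      "required": ["labels", "r", "p", "flags"]
    },
    "screen": {
      "type": "object",
      "required": ["applied", "threshold", "mean_terms"]
    },
    "glm": { "$ref": "#/$defs/fit_block" },
    "joint": { "$ref": "#/$defs/fit_block" },
    "comparison": {
      "type": "object",
      "required": ["table", "best", "overall"]
    },
    "diagnostics": {
      "type": "object",
      "required": ["glm", "joint"],
      "properties": {
        "glm": { "$ref": "#/$defs/diag_block" },
        "joint": { "$ref": "#/$defs/diag_block" }
      }
    }
  },
  "$defs": {
    "fit_block": {
      "type": "object",
      "required": ["mean_coefficients", "dispersion_coefficients",
                   "criteria", "converged", "n_iter", "method"]
    },
    "diag_block": {
      "type": "object",
      "required": ["fitted", "std_resid", "abs_resid", "running_mean",
                   "qq", "hist"]
    }
  }
}
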