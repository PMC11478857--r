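{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sonoyeast pipeline summary",
  "type": "object",
  "required": ["regressions", "x50_um", "n_regressions"],
  "properties": {
    "regressions": {
      "type": "object",
      "description": "Per strain: named OLS fits with slope, intercept, r_squared, n"
    },
    "x50_um": {
      "type": "object",
      "description": "Per strain: volume-weighted median particle size in um"
    },
    "phase_comparison": {
      "type": "object",
      "description": "Per strain and response: ANOVA p-value and compact letter display"
    },
    "n_regressions": {
      "type": "integer",
      "description": "Total number of regressions fitted"
    }
  }
}
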