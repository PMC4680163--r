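{
  "description": "Structural schema for study report summary.json",
  "required_fields": {
    "n_phantoms": "number",
    "n_observers": "number",
    "n_sessions": "number",
    "seed": "number",
    "config_hash": "string",
    "method_comparison": "table",
    "icc": "table"
  }
}
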