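{
  "fields": [
    {"name": "pipeline", "type": "list"},
    {"name": "seeds", "type": "list"},
    {"name": "priors", "type": "list"},
    {"name": "ratio", "type": "list"},
    {"name": "notes", "type": "string"}
  ],
  "ratio_fields": [
    {"name": "mean", "type": "number"},
    {"name": "sd", "type": "number"},
    {"name": "ci", "type": "number"},
    {"name": "reduction_mean", "type": "number"},
    {"name": "reduction_range", "type": "number"},
    {"name": "ne_mean", "type": "number"},
    {"name": "nef_mean", "type": "number"},
    {"name": "n_samples", "type": "number"},
    {"name": "mode", "type": "string"},
    {"name": "analytic_mean", "type": "number"}
  ]
}
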