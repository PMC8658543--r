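{
  "schema": "arcnet culture result summary",
  "version": "1.0",
  "required_fields": {
    "schema_version": "string",
    "n_rois": "number",
    "n_neuronal": "number",
    "mean_ci": "object",
    "ci_change": "object",
    "mean_rate_change": "object",
    "arc_pct": "number",
    "cfos_pct": "number",
    "icd_metrics": "object",
    "refined": "boolean",
    "thresholds": "object",
    "params": "object"
  }
}
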