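{
  "title": "predstab stability report, version 1",
  "required": {
    "schema": {"type": "string"},
    "provenance": {
      "type": "object",
      "required": {
        "strategy": {"type": "object"},
        "master_seed": {"type": "number"},
        "B_requested": {"type": "number"},
        "B_successful": {"type": "number"}
      }
    },
    "n": {"type": "number"},
    "average_mape": {"type": "number"},
    "mape_quantiles": {"type": "object"},
    "c_orig": {"type": "number"},
    "c_boot_summary": {
      "type": "object",
      "required": {
        "min": {"type": "number"},
        "p2.5": {"type": "number"},
        "median": {"type": "number"},
        "p97.5": {"type": "number"},
        "max": {"type": "number"}
      }
    }
  }
}
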