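{
  "name": "Miettinen-Lasota (AFIP) GIST risk classification",
  "site_groups": {
    "colon-rectum": "rectum",
    "duodenum": "duodenum",
    "small-intestine": "jejunum-ileum",
    "stomach": "stomach"
  },
  "size_breaks_cm": [2, 5, 10],
  "mitotic_threshold_per_5mm2": 5,
  "classes": {
    "stomach": {
      "low_mitoses": ["none", "very_low", "low", "moderate"],
      "high_mitoses": ["none", "moderate", "high", "high"]
    },
    "duodenum": {
      "low_mitoses": ["none", "low", "insufficient_data", "high"],
      "high_mitoses": ["insufficient_data", "high", "insufficient_data", "high"]
    },
    "jejunum-ileum": {
      "low_mitoses": ["none", "low", "moderate", "high"],
      "high_mitoses": ["high", "high", "high", "high"]
    },
    "rectum": {
      "low_mitoses": ["none", "very_low", "insufficient_data", "high"],
      "high_mitoses": ["high", "high", "high", "high"]
    }
  }
}
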