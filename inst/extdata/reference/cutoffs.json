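[
  {"lower": 0.00, "upper": 0.25, "label": "PM"},
  {"lower": 0.25, "upper": 1.00, "label": "IM"},
  {"lower": 1.00, "upper": 2.25, "label": "NM"},
  {"lower": 2.25, "upper": null, "label": "UM"}
]
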