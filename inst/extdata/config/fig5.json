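{
  "kind": "scan",
  "comment": "Conductance scans: every mechanism's maximal conductance varied one-by-one over 0.3x to 10x its default.  The maximal current is 0.8 nA (the design text prints '0.8 pA' once; surrounding current axes make clear nA is meant).",
  "axis": "conductance:*",
  "values": [0.3, 1.0, 3.0, 10.0],
  "I_cap": 0.8,
  "probes": [0.2, 0.4]
}
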