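{
  "kind": "scan",
  "comment": "f-I curves for selected cm values with cm altered on the soma and proximal dendrites only; the relative f difference between the 1.0cm and 1.5cm curves is evaluated at the largest current with sustained firing in both.",
  "axis": "cm",
  "cm_region": "sprx",
  "values": [1.0, 1.25, 1.5],
  "probes": [0.2, 0.4]
}
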