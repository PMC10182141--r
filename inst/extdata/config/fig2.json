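{
  "kind": "scan",
  "comment": "Firing properties vs specific membrane capacitance: thresholds, rates and spike widths at the 0.2/0.4 nA probe currents for cm/cm0 factors spanning the experimentally motivated range.",
  "axis": "cm",
  "cm_region": "all",
  "values": [0.5, 0.75, 1.0, 1.25, 1.5, 2.0],
  "probes": [0.2, 0.4]
}
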