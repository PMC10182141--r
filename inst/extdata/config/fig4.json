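{
  "kind": "scan",
  "comment": "Reversal-potential scans: every ionic reversal shifted separately by up to +/-20 mV (calcium expressed through the fixed extracellular concentration setting E_Ca at t = 0).  10 mV steps between -20 and +20 are a package choice; the source design shows the endpoints graphically.",
  "axis": "reversal:*",
  "values": [-20, -10, 0, 10, 20],
  "probes": [0.2, 0.4]
}
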