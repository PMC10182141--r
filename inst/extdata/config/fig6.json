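{
  "kind": "scenarios",
  "comment": "Combinatorial candidate-mechanism scenarios: cm x1.5 on soma+proximal dendrites, E_Na +10 mV (53 -> 63 mV), extracellular calcium x10 (E_Ca(0): 131.06 -> 161.53 mV), and Kv2like/SK conductance factors between 1.5 and 4.",
  "scenarios": [
    {"cm_factor": 1.5, "cm_region": "sprx",
     "e_shifts": {"na": 10},
     "g_factors": {"Kv2like": 2, "SK": 2},
     "label": "cm1.5+ENa10+Kv2like2+SK2"},
    {"cm_factor": 1.5, "cm_region": "sprx",
     "ca_out_factor": 10,
     "g_factors": {"SK": 3},
     "label": "cm1.5+ECa30+SK3"},
    {"cm_factor": 1.5, "cm_region": "sprx",
     "ca_out_factor": 10,
     "g_factors": {"Kv2like": 2, "SK": 2},
     "label": "cm1.5+ECa30+Kv2like2+SK2"},
    {"cm_factor": 1.5, "cm_region": "sprx",
     "g_factors": {"Kv2like": 4, "SK": 4},
     "label": "cm1.5+Kv2like4+SK4"},
    {"cm_factor": 1.5, "cm_region": "sprx",
     "ca_out_factor": 10,
     "e_shifts": {"na": 10},
     "g_factors": {"Kv2like": 3, "SK": 3},
     "label": "cm1.5+ECa30+ENa10+Kv2like3+SK3"}
  ]
}
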