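{
  "name": "hh",
  "temperature_C": 6.3,
  "mechanisms": [
    {
      "name": "na_hh", "kind": "gated", "gbar": 0.12, "erev": 50,
      "ion": "na", "q10": 3, "tref_C": 6.3,
      "gates": [
        {"name": "m", "exponent": 3,
         "alpha": {"form": "exp_linear", "rate": 0.1, "vhalf": -40, "scale": 10},
         "beta": {"form": "exponential", "rate": 4.0, "vhalf": -65, "scale": -18}},
        {"name": "h", "exponent": 1,
         "alpha": {"form": "exponential", "rate": 0.07, "vhalf": -65, "scale": -20},
         "beta": {"form": "sigmoid", "rate": 1.0, "vhalf": -35, "scale": 10}}
      ]
    },
    {
      "name": "k_hh", "kind": "gated", "gbar": 0.036, "erev": -77,
      "ion": "k", "q10": 3, "tref_C": 6.3,
      "gates": [
        {"name": "n", "exponent": 4,
         "alpha": {"form": "exp_linear", "rate": 0.01, "vhalf": -55, "scale": 10},
         "beta": {"form": "exponential", "rate": 0.125, "vhalf": -65, "scale": -80}}
      ]
    },
    {"name": "leak", "kind": "leak", "gbar": 0.0003, "erev": -54.3, "ion": "leak"}
  ]
}
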