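{
  "name": "toy_allen",
  "comment": "Synthetic stand-in kinetics for the eleven-mechanism perisomatic PV-cell inventory.  NaV/Kv3_1 use fast-spiking interneuron kinetics (Wang-Buzsaki style, Type I excitability); Ca_HVA uses standard HVA calcium kinetics; the remaining channels are schematic sigmoid/constant-tau stand-ins.  This is NOT a database transcription: it exists so the full pipeline is testable without downloads.",
  "temperature_C": 34,
  "ca_pool": {
    "gamma": 0.05,
    "depth": 0.1,
    "tau": 80,
    "ca_rest": 0.0001,
    "ca_out": 2
  },
  "mechanisms": [
    {
      "name": "Ih",
      "kind": "gated",
      "gbar": 1e-05,
      "erev": -45,
      "ion": "nonspecific",
      "gates": [
        {
          "name": "q",
          "exponent": 1,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -80,
            "scale": -8
          },
          "tau": {
            "form": "constant",
            "rate": 50
          }
        }
      ]
    },
    {
      "name": "NaV",
      "kind": "gated",
      "gbar": 0.05,
      "erev": 53,
      "ion": "na",
      "gates": [
        {
          "name": "m",
          "exponent": 3,
          "instantaneous": true,
          "alpha": {
            "form": "exp_linear",
            "rate": 0.1,
            "vhalf": -35,
            "scale": 10
          },
          "beta": {
            "form": "exponential",
            "rate": 4.0,
            "vhalf": -60,
            "scale": -18
          }
        },
        {
          "name": "h",
          "exponent": 1,
          "alpha": {
            "form": "exponential",
            "rate": 0.35,
            "vhalf": -58,
            "scale": -20
          },
          "beta": {
            "form": "sigmoid",
            "rate": 5.0,
            "vhalf": -28,
            "scale": 10
          }
        }
      ]
    },
    {
      "name": "Kd",
      "kind": "markov",
      "gbar": 5e-05,
      "erev": -90,
      "ion": "k",
      "markov": {
        "states": [
          "C",
          "O"
        ],
        "conducting": [
          "O"
        ],
        "transitions": [
          {
            "from": "C",
            "to": "O",
            "rate": {
              "form": "sigmoid",
              "rate": 0.02,
              "vhalf": -50,
              "scale": 15
            }
          },
          {
            "from": "O",
            "to": "C",
            "rate": {
              "form": "sigmoid",
              "rate": 0.02,
              "vhalf": -50,
              "scale": -15
            }
          }
        ]
      }
    },
    {
      "name": "Kv2like",
      "kind": "gated",
      "gbar": 0.002,
      "erev": -90,
      "ion": "k",
      "gates": [
        {
          "name": "n",
          "exponent": 2,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -9,
            "scale": 11
          },
          "tau": {
            "form": "constant",
            "rate": 15
          }
        }
      ]
    },
    {
      "name": "K_T",
      "kind": "gated",
      "gbar": 0.0001,
      "erev": -90,
      "ion": "k",
      "gates": [
        {
          "name": "m",
          "exponent": 1,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -47,
            "scale": 29
          },
          "tau": {
            "form": "constant",
            "rate": 1
          }
        },
        {
          "name": "h",
          "exponent": 1,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -66,
            "scale": -10
          },
          "tau": {
            "form": "constant",
            "rate": 15
          }
        }
      ]
    },
    {
      "name": "Kv3_1",
      "kind": "gated",
      "gbar": 0.018,
      "erev": -90,
      "ion": "k",
      "gates": [
        {
          "name": "n",
          "exponent": 4,
          "alpha": {
            "form": "exp_linear",
            "rate": 0.05,
            "vhalf": -34,
            "scale": 10
          },
          "beta": {
            "form": "exponential",
            "rate": 0.625,
            "vhalf": -44,
            "scale": -80
          }
        }
      ]
    },
    {
      "name": "Im_v2",
      "kind": "gated",
      "gbar": 2e-05,
      "erev": -90,
      "ion": "k",
      "gates": [
        {
          "name": "m",
          "exponent": 1,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -45,
            "scale": 10
          },
          "tau": {
            "form": "constant",
            "rate": 50
          }
        }
      ]
    },
    {
      "name": "SK",
      "kind": "sk",
      "gbar": 0.001,
      "erev": -90,
      "ion": "k",
      "sk": {
        "kd": 0.00043,
        "hill": 4.8
      }
    },
    {
      "name": "Ca_HVA",
      "kind": "gated",
      "gbar": 0.0001,
      "ion": "ca",
      "writes_ca": true,
      "gates": [
        {
          "name": "m",
          "exponent": 2,
          "alpha": {
            "form": "exp_linear",
            "rate": 0.055,
            "vhalf": -27,
            "scale": 3.8
          },
          "beta": {
            "form": "exponential",
            "rate": 0.94,
            "vhalf": -75,
            "scale": -17
          }
        },
        {
          "name": "h",
          "exponent": 1,
          "alpha": {
            "form": "exponential",
            "rate": 0.000457,
            "vhalf": -13,
            "scale": -50
          },
          "beta": {
            "form": "sigmoid",
            "rate": 0.0065,
            "vhalf": -15,
            "scale": 28
          }
        }
      ]
    },
    {
      "name": "Ca_LVA",
      "kind": "gated",
      "gbar": 1e-05,
      "ion": "ca",
      "writes_ca": true,
      "gates": [
        {
          "name": "m",
          "exponent": 2,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -40,
            "scale": 6
          },
          "tau": {
            "form": "constant",
            "rate": 5
          }
        },
        {
          "name": "h",
          "exponent": 1,
          "inf": {
            "form": "sigmoid",
            "rate": 1.0,
            "vhalf": -60,
            "scale": -6
          },
          "tau": {
            "form": "constant",
            "rate": 20
          }
        }
      ]
    },
    {
      "name": "leak",
      "kind": "leak",
      "gbar": 0.0001,
      "erev": -65,
      "ion": "leak"
    }
  ]
}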