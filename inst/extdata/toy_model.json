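{
  "format": "maxentcc-model-v1",
  "budget": "inf",
  "biomass": {
    "kind": "affine",
    "weights": {
      "v_atp": 1
    },
    "e": 1,
    "y": 348
  },
  "metabolites": [
    {
      "id": "glc",
      "e": 0,
      "y": 0,
      "exchange": true,
      "excretable": false
    },
    {
      "id": "lac",
      "e": 0,
      "y": 0,
      "exchange": true,
      "excretable": true
    },
    {
      "id": "intermediate",
      "e": 0,
      "y": 0,
      "exchange": false,
      "excretable": false
    },
    {
      "id": "atp",
      "e": 0,
      "y": 0,
      "exchange": false,
      "excretable": false
    }
  ],
  "reactions": [
    {
      "id": "v_g",
      "stoich": {
        "glc": -1,
        "intermediate": 2,
        "atp": 2
      },
      "lb": "0",
      "ub": "0.5",
      "alpha": 0
    },
    {
      "id": "v_l",
      "stoich": {
        "lac": -1,
        "intermediate": 1
      },
      "lb": "-inf",
      "ub": "0",
      "alpha": 0
    },
    {
      "id": "v_o",
      "stoich": {
        "intermediate": -1,
        "atp": 18
      },
      "lb": "0",
      "ub": "0.45",
      "alpha": 0
    },
    {
      "id": "v_atp",
      "stoich": {
        "atp": -1
      },
      "lb": "0",
      "ub": "inf",
      "alpha": 0
    }
  ]
}
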