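{
  "species": [
    {
      "id": "AA",
      "molar_mass": "1"
    },
    {
      "id": "E1",
      "molar_mass": "1"
    },
    {
      "id": "E2",
      "molar_mass": "1"
    },
    {
      "id": "R",
      "molar_mass": "1"
    }
  ],
  "reactions": [
    {
      "id": "v1",
      "stoich": {
        "AA": "1"
      },
      "irreversible": true,
      "exchange": true,
      "catalyst": "E1"
    },
    {
      "id": "v2",
      "stoich": {
        "AA": "1"
      },
      "irreversible": true,
      "exchange": true,
      "catalyst": "E2"
    },
    {
      "id": "w1",
      "stoich": {
        "AA": "-1",
        "E1": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "w2",
      "stoich": {
        "AA": "-1",
        "E2": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "wR",
      "stoich": {
        "AA": "-1",
        "R": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    }
  ]
}
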