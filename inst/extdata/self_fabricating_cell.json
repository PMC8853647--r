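{
  "species": [
    {
      "id": "G",
      "molar_mass": "180"
    },
    {
      "id": "N",
      "molar_mass": "18"
    },
    {
      "id": "AA",
      "molar_mass": "198"
    },
    {
      "id": "LD",
      "molar_mass": "1260"
    },
    {
      "id": "L",
      "molar_mass": "1260"
    },
    {
      "id": "IG",
      "molar_mass": "127908"
    },
    {
      "id": "IN",
      "molar_mass": "127908"
    },
    {
      "id": "EAA",
      "molar_mass": "64350"
    },
    {
      "id": "ELD",
      "molar_mass": "64350"
    },
    {
      "id": "EL",
      "molar_mass": "64350"
    },
    {
      "id": "R",
      "molar_mass": "4476384"
    }
  ],
  "reactions": [
    {
      "id": "r_IG",
      "stoich": {
        "G": "1"
      },
      "irreversible": true,
      "exchange": true,
      "catalyst": "IG"
    },
    {
      "id": "r_IN",
      "stoich": {
        "N": "1"
      },
      "irreversible": true,
      "exchange": true,
      "catalyst": "IN"
    },
    {
      "id": "r_EAA",
      "stoich": {
        "G": "-1",
        "N": "-1",
        "AA": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "EAA"
    },
    {
      "id": "r_ELD",
      "stoich": {
        "G": "-7",
        "LD": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "ELD"
    },
    {
      "id": "r_EL",
      "stoich": {
        "LD": "-1",
        "L": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "EL"
    },
    {
      "id": "s_IG",
      "stoich": {
        "AA": "-646",
        "IG": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "s_IN",
      "stoich": {
        "AA": "-646",
        "IN": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "s_EAA",
      "stoich": {
        "AA": "-325",
        "EAA": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "s_ELD",
      "stoich": {
        "AA": "-325",
        "ELD": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "s_EL",
      "stoich": {
        "AA": "-325",
        "EL": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    },
    {
      "id": "s_R",
      "stoich": {
        "AA": "-22608",
        "R": "1"
      },
      "irreversible": true,
      "exchange": false,
      "catalyst": "R"
    }
  ]
}
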