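{
  "metabolites": [
    {
      "id": "ph",
      "name": "photon",
      "balanced": true
    },
    {
      "id": "no3",
      "name": "internal nitrate",
      "balanced": true
    },
    {
      "id": "atp",
      "name": "ATP",
      "balanced": true
    },
    {
      "id": "ch2o",
      "name": "carbon skeleton",
      "balanced": true
    },
    {
      "id": "ncar",
      "name": "nitrogen carrier",
      "balanced": true
    },
    {
      "id": "chl",
      "name": "chlorophyll store",
      "balanced": false
    },
    {
      "id": "car",
      "name": "beta-carotene store",
      "balanced": false
    },
    {
      "id": "bio",
      "name": "biomass",
      "balanced": false
    }
  ],
  "reactions": [
    {
      "id": "EX_photon",
      "name": "photon exchange",
      "stoichiometry": {
        "ph": -1
      },
      "lb": -1000,
      "ub": 0,
      "role": "photon"
    },
    {
      "id": "EX_no3",
      "name": "nitrate metabolization",
      "stoichiometry": {
        "no3": -1
      },
      "lb": -0.19,
      "ub": 0,
      "role": "nitrate_met"
    },
    {
      "id": "PSY",
      "name": "photosynthesis (linear)",
      "stoichiometry": {
        "ph": -20,
        "atp": 1,
        "ch2o": 1
      },
      "lb": 0,
      "ub": "Inf"
    },
    {
      "id": "CEF",
      "name": "cyclic electron flow",
      "stoichiometry": {
        "ph": -10,
        "atp": 1
      },
      "lb": 0,
      "ub": "Inf"
    },
    {
      "id": "ASM",
      "name": "nitrate assimilation",
      "stoichiometry": {
        "no3": -1,
        "atp": -1,
        "ch2o": -1,
        "ncar": 1
      },
      "lb": 0,
      "ub": "Inf"
    },
    {
      "id": "ACC_chl",
      "name": "chlorophyll accumulation",
      "stoichiometry": {
        "atp": -1,
        "ch2o": -1,
        "ncar": -1,
        "chl": 1
      },
      "lb": 0,
      "ub": "Inf",
      "role": "chl_acc"
    },
    {
      "id": "ACC_car",
      "name": "beta-carotene accumulation",
      "stoichiometry": {
        "atp": -2,
        "ch2o": -4,
        "car": 1
      },
      "lb": 0,
      "ub": "Inf",
      "role": "car_acc"
    },
    {
      "id": "NGAM",
      "name": "ATP maintenance",
      "stoichiometry": {
        "atp": -1
      },
      "lb": 0.183,
      "ub": "Inf",
      "role": "ngam"
    },
    {
      "id": "BIO",
      "name": "growth",
      "stoichiometry": {
        "atp": -30,
        "ch2o": -40,
        "ncar": -3.5,
        "chl": -0.027,
        "car": -0.0014,
        "bio": 1
      },
      "lb": 0,
      "ub": "Inf",
      "role": "biomass"
    }
  ]
}
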