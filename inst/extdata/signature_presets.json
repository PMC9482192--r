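{
  "library_version": "1.0",
  "presets": [
    {
      "id": "hv_leaf_nacl_250", "species": "barley", "tissue": "leaf",
      "stimulus": "NaCl", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 5e-7, "onset": 0, "ttp": 18.5,
      "decay_half": 8, "sustained": 0,
      "dose_threshold": 25, "dose_halfsat": 100, "inhibition": 0.8
    },
    {
      "id": "hv_root_nacl_250", "species": "barley", "tissue": "root",
      "stimulus": "NaCl", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 5e-7, "onset": 0, "ttp": 8.5,
      "decay_half": 10, "sustained": 0,
      "dose_threshold": 25, "dose_halfsat": 100, "inhibition": 0.8
    },
    {
      "id": "at_leaf_nacl_250", "species": "arabidopsis", "tissue": "leaf",
      "stimulus": "NaCl", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 7e-7, "onset": 0, "ttp": 18.5,
      "decay_half": 8, "sustained": 0,
      "dose_threshold": 25, "dose_halfsat": 100
    },
    {
      "id": "at_root_nacl_250", "species": "arabidopsis", "tissue": "root",
      "stimulus": "NaCl", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 5e-7, "onset": 0, "ttp": 8.5,
      "decay_half": 8, "sustained": 0,
      "osc_amp": 7.5e-8, "osc_period": 60, "osc_damp": 80, "osc_count": 3,
      "dose_threshold": 25, "dose_halfsat": 100
    },
    {
      "id": "hv_leaf_mannitol_250", "species": "barley", "tissue": "leaf",
      "stimulus": "mannitol", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 0, "onset": 0, "ttp": 10,
      "decay_half": 10, "sustained": 0,
      "dose_threshold": 50, "dose_halfsat": 100
    },
    {
      "id": "at_leaf_mannitol_250", "species": "arabidopsis", "tissue": "leaf",
      "stimulus": "mannitol", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 0, "onset": 0, "ttp": 10,
      "decay_half": 10, "sustained": 0,
      "dose_threshold": 50, "dose_halfsat": 100
    },
    {
      "id": "hv_root_mannitol_250", "species": "barley", "tissue": "root",
      "stimulus": "mannitol", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 8e-8, "onset": 0, "ttp": 9.5,
      "decay_half": 12, "sustained": 2e-8,
      "dose_threshold": 50, "dose_halfsat": 100, "inhibition": 0.98
    },
    {
      "id": "at_root_mannitol_250", "species": "arabidopsis", "tissue": "root",
      "stimulus": "mannitol", "dose": 250, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 5e-7, "onset": 0, "ttp": 9.5,
      "decay_half": 8, "sustained": 0,
      "osc_amp": 7.5e-8, "osc_period": 60, "osc_damp": 80, "osc_count": 3,
      "dose_threshold": 50, "dose_halfsat": 100
    },
    {
      "id": "hv_leaf_h2o2_10", "species": "barley", "tissue": "leaf",
      "stimulus": "H2O2", "dose": 10, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 4e-7, "onset": 15, "ttp": 40,
      "decay_half": 25, "sustained": 1e-7,
      "dose_threshold": 1, "dose_halfsat": 4, "dose_decline": 0.5,
      "inhibition": 0.6
    },
    {
      "id": "hv_root_h2o2_10", "species": "barley", "tissue": "root",
      "stimulus": "H2O2", "dose": 10, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 4e-7, "onset": 15, "ttp": 40,
      "decay_half": 25, "sustained": 1e-7,
      "dose_threshold": 1, "dose_halfsat": 4, "dose_decline": 0.5,
      "inhibition": 0.6
    },
    {
      "id": "at_leaf_h2o2_10", "species": "arabidopsis", "tissue": "leaf",
      "stimulus": "H2O2", "dose": 10, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 2e-7, "onset": 15, "ttp": 50,
      "decay_half": 40, "sustained": 5e-8,
      "dose_threshold": 1, "dose_halfsat": 6, "dose_decline": 0.5
    },
    {
      "id": "at_root_h2o2_10", "species": "arabidopsis", "tissue": "root",
      "stimulus": "H2O2", "dose": 10, "dose_units": "mM",
      "baseline": 1e-7, "amplitude": 2.5e-7, "onset": 15, "ttp": 40,
      "decay_half": 30, "sustained": 5e-8,
      "dose_threshold": 1, "dose_halfsat": 6, "dose_decline": 0.5
    },
    {
      "id": "hv_leaf_flg22_200", "species": "barley", "tissue": "leaf",
      "stimulus": "flg22", "dose": 200, "dose_units": "nM",
      "baseline": 1e-7, "amplitude": 5e-8, "onset": 90, "ttp": 300,
      "decay_half": 400, "sustained": 0,
      "dose_threshold": 100, "dose_halfsat": 150, "inhibition": 0.9
    },
    {
      "id": "at_leaf_flg22_200", "species": "arabidopsis", "tissue": "leaf",
      "stimulus": "flg22", "dose": 200, "dose_units": "nM",
      "baseline": 1e-7, "amplitude": 5e-8, "onset": 60, "ttp": 190,
      "decay_half": 400, "sustained": 0,
      "dose_threshold": 50, "dose_halfsat": 100
    },
    {
      "id": "hv_root_flg22_200", "species": "barley", "tissue": "root",
      "stimulus": "flg22", "dose": 200, "dose_units": "nM",
      "baseline": 1e-7, "amplitude": 0, "onset": 90, "ttp": 300,
      "decay_half": 400, "sustained": 0,
      "dose_threshold": 100, "dose_halfsat": 150
    },
    {
      "id": "at_root_flg22_200", "species": "arabidopsis", "tissue": "root",
      "stimulus": "flg22", "dose": 200, "dose_units": "nM",
      "baseline": 1e-7, "amplitude": 0, "onset": 60, "ttp": 190,
      "decay_half": 400, "sustained": 0,
      "dose_threshold": 50, "dose_halfsat": 100
    }
  ]
}
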