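{
  "example1": {
    "constructor": "selection_example_config", "args": {"example": 1},
    "description": "Selection study: 30 correlated markers, proportional-odds outcome, prevalences 0.6/0.3/0.1, slopes (1, 2, 0.5 x14, 0.1 x14)."
  },
  "example2": {
    "constructor": "selection_example_config", "args": {"example": 2},
    "description": "As example1 with prevalences 0.6/0.335/0.065."
  },
  "example3": {
    "constructor": "selection_example_config", "args": {"example": 3},
    "description": "Selection study: conditional-Gaussian levels, level-2 means (1.5, 1, 0.5 x14, 0.1 x14), level-3 means (2, 2, 0.8 x14, 0.1 x14)."
  },
  "example4": {
    "constructor": "selection_example_config", "args": {"example": 4},
    "description": "As example3 with level-2 mean 1 for marker 1 and level-3 means 0.2 for markers 17-30."
  },
  "example5": {
    "constructor": "selection_example_config", "args": {"example": 5},
    "description": "As example4 with level-2 means 0 for markers 17-30."
  },
  "np_K3_mu-1": {"constructor": "construction_scenario", "args": {"K": 3, "mu": -1}, "description": "Construction study, non-proportional-odds, K=3, level-2 mean -1."},
  "np_K3_mu0":  {"constructor": "construction_scenario", "args": {"K": 3, "mu": 0},  "description": "Construction study, non-proportional-odds, K=3, level-2 mean 0."},
  "np_K3_mu1":  {"constructor": "construction_scenario", "args": {"K": 3, "mu": 1},  "description": "Construction study, non-proportional-odds, K=3, level-2 mean 1."},
  "np_K3_mu2":  {"constructor": "construction_scenario", "args": {"K": 3, "mu": 2},  "description": "Construction study, non-proportional-odds, K=3, level-2 mean 2."},
  "np_K3_mu3":  {"constructor": "construction_scenario", "args": {"K": 3, "mu": 3},  "description": "Construction study, non-proportional-odds, K=3, level-2 mean 3."},
  "np_K5_mu-1": {"constructor": "construction_scenario", "args": {"K": 5, "mu": -1}, "description": "Construction study, non-proportional-odds, K=5, level-4 mean -1."},
  "np_K5_mu0":  {"constructor": "construction_scenario", "args": {"K": 5, "mu": 0},  "description": "Construction study, non-proportional-odds, K=5, level-4 mean 0."},
  "np_K5_mu1":  {"constructor": "construction_scenario", "args": {"K": 5, "mu": 1},  "description": "Construction study, non-proportional-odds, K=5, level-4 mean 1."},
  "np_K5_mu2":  {"constructor": "construction_scenario", "args": {"K": 5, "mu": 2},  "description": "Construction study, non-proportional-odds, K=5, level-4 mean 2."},
  "np_K5_mu3":  {"constructor": "construction_scenario", "args": {"K": 5, "mu": 3},  "description": "Construction study, non-proportional-odds, K=5, level-4 mean 3."},
  "po_K3_b12":  {"constructor": "construction_po_scenario", "args": {"K": 3, "beta": [1, 2]},   "description": "Construction study, proportional-odds holds, K=3, slopes (1, 2)."},
  "po_K3_b115": {"constructor": "construction_po_scenario", "args": {"K": 3, "beta": [1, 1.5]}, "description": "Construction study, proportional-odds holds, K=3, slopes (1, 1.5)."},
  "po_K3_bm11": {"constructor": "construction_po_scenario", "args": {"K": 3, "beta": [-1, 1]},  "description": "Construction study, proportional-odds holds, K=3, slopes (-1, 1)."},
  "po_K5_b12":  {"constructor": "construction_po_scenario", "args": {"K": 5, "beta": [1, 2]},   "description": "Construction study, proportional-odds holds, K=5, slopes (1, 2)."},
  "po_K5_b115": {"constructor": "construction_po_scenario", "args": {"K": 5, "beta": [1, 1.5]}, "description": "Construction study, proportional-odds holds, K=5, slopes (1, 1.5)."},
  "po_K5_bm11": {"constructor": "construction_po_scenario", "args": {"K": 5, "beta": [-1, 1]},  "description": "Construction study, proportional-odds holds, K=5, slopes (-1, 1)."}
}
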