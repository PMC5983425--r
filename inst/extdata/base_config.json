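{
  "margins": {
    "p_pos_st": 0.3,
    "p_pos_ifmi": 0.1,
    "p_pos_second": 0.1,
    "psa_mode": "fixed_rr"
  },
  "costs": {
    "drg_cost": 3508,
    "lost_productivity": 521,
    "agent_cost": 500,
    "device_price": 150000,
    "maintenance_rate": 0.1,
    "device_lifespan": 7,
    "surgeries_per_year": 200,
    "draping_cost": 23,
    "staff_addon_cost": 107,
    "st_duration": 59,
    "prolongation": 10,
    "fsa_duration": 27,
    "staff_time_saving_factor": 0.64,
    "cost_per_minute": 68.2291666666667,
    "fsa_fixed_saving": 92.0545238095238,
    "working_days_lost": 14
  },
  "psa": {
    "p_pos_st": {
      "kind": "beta",
      "mean": 0.3,
      "se": 0.051
    },
    "p_pos_ifmi": {
      "kind": "beta",
      "mean": 0.1,
      "se": 0.018
    },
    "p_pos_second": {
      "kind": "beta",
      "mean": 0.1,
      "se": 0.018
    },
    "drg_cost": {
      "kind": "gamma",
      "mean": 3508,
      "se": 175
    },
    "lost_productivity": {
      "kind": "gamma",
      "mean": 521,
      "se": 52
    },
    "agent_cost": {
      "kind": "gamma",
      "mean": 500,
      "se": 25
    },
    "device_cost": {
      "kind": "gamma",
      "mean": 182.142857142857,
      "se": 18
    },
    "draping_cost": {
      "kind": "gamma",
      "mean": 23,
      "se": 2
    },
    "staff_addon_cost": {
      "kind": "gamma",
      "mean": 107,
      "se": 5
    },
    "st_duration": {
      "kind": "triangular",
      "mean": 59,
      "min": 35,
      "max": 83
    },
    "prolongation": {
      "kind": "triangular",
      "mean": 10,
      "min": 5,
      "max": 15
    },
    "fsa_duration": {
      "kind": "triangular",
      "mean": 27,
      "min": 13,
      "max": 53
    },
    "staff_time_saving_factor": {
      "kind": "fixed",
      "mean": 0.64
    }
  },
  "run": {
    "n_draws": 10000,
    "seed": 1,
    "tornado_fraction": 0.25
  }
}
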