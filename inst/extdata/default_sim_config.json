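{
  "n_strains": 59,
  "mice_per_strain_per_arm": 8,
  "var_strain": 1000000,
  "var_strain_slope": 40000,
  "var_mouse": 250000,
  "var_resid": 1000000,
  "grand_mean": 4000,
  "day_effects": [0, 0, 0, 0, 0, 0, 0, 0, 0],
  "cocaine_acute_effect": 3000,
  "ramp": [0, 600, 500, 400, 300],
  "expression_effect": 0,
  "conditioned_effect": 500,
  "sex_effect": 300,
  "site_effect": 500,
  "sex_ratio": 0.5,
  "site_assignment": "JAX",
  "seed": 1
}
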