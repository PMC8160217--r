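{
  "ambient": {
    "vapor_diffusivity": 2.5e-05,
    "saturated_vapor_concentration": 0.023,
    "relative_humidity": 0.6
  },
  "droplet": {
    "volume_uL": 0.5,
    "contact_angle_deg": 45
  },
  "fluid": {
    "density": 1030,
    "viscosity": 0.003,
    "gamma_ref": 0.064,
    "w_peg_ref": 0.05,
    "gamma_slope": -0.05
  },
  "binodal": {
    "source": "synthetic",
    "tie_slope": -0.55
  },
  "pathway": {
    "c0_wt_pct": [9, 4],
    "delta_r_fraction": 0.05,
    "delta_t": 5,
    "n_steps": 3,
    "solution_density": 1030
  },
  "evaporation": {
    "delta_t": 5,
    "n_steps": 60
  },
  "ribozyme": {
    "D": 1e-10,
    "kcat": 0.017,
    "K_M": 0.0001,
    "e_bulk": 1e-05,
    "s_bulk": 0.0001,
    "R_d": 1e-05,
    "K_E": 50,
    "K_S": 5,
    "K_P": 1,
    "n_nodes": 120,
    "n_save": 150
  },
  "seed": 1
}
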