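{
  "seed": 20231,
  "design": {
    "groups": [
      {"label": "BSR 0.15 mg/kg", "formulation": "BSR", "dose_mg_per_kg": 0.15, "n": 8},
      {"label": "EXR 0.1 mg/kg",  "formulation": "EXR", "dose_mg_per_kg": 0.1,  "n": 6},
      {"label": "EXR 0.15 mg/kg", "formulation": "EXR", "dose_mg_per_kg": 0.15, "n": 3},
      {"label": "EXR 0.2 mg/kg",  "formulation": "EXR", "dose_mg_per_kg": 0.2,  "n": 8}
    ],
    "schedule_h": [0.25, 0.5, 1, 8, 24, 48, 72],
    "lloq_ng_per_ml": 0.1,
    "threshold_ng_per_ml": 0.1
  },
  "population": {
    "typical": {
      "clearance_over_F": 1.8,
      "volume_over_F": 55,
      "ka_fast": 0.9,
      "ka_slow": 0.12,
      "frac_fast": 0.5
    },
    "bsv_cv": {
      "clearance_over_F": 0.3,
      "volume_over_F": 0.3,
      "ka_fast": 0.5,
      "ka_slow": 0.5
    },
    "residual_cv": 0.15,
    "metabolite": {"fm": 0.35, "volume_m_over_F": 60, "ke_m": 0.05}
  },
  "nca": {
    "lambda_z_min_points": 3,
    "adj_r2_tol": 1e-4,
    "clast_mode": "observed",
    "extrapolation_warn_pct": 20,
    "threshold": 0.1
  },
  "comparisons": {
    "parameters": ["cmax", "tmax", "t_half", "auc_last", "auc_inf",
                   "clearance_over_F", "lambda_z", "mrt_last", "mrt_inf"],
    "pairs": [
      ["BSR 0.15 mg/kg", "EXR 0.1 mg/kg"],
      ["BSR 0.15 mg/kg", "EXR 0.15 mg/kg"],
      ["BSR 0.15 mg/kg", "EXR 0.2 mg/kg"]
    ],
    "family_size": 1,
    "alpha": 0.05
  }
}
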