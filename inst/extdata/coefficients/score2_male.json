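{
  "model": "score2",
  "stratum": {"sex": "male"},
  "units": {"chol": "mmol/L", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "identity", "coef": 0.3742, "center": 60, "scale": 5},
    {"name": "current_smoker", "transform": "identity", "coef": 0.6012},
    {"name": "systolic_bp", "transform": "identity", "coef": 0.2777, "center": 120, "scale": 20},
    {"name": "total_chol", "transform": "identity", "coef": 0.1458, "center": 6, "scale": 1},
    {"name": "hdl_chol", "transform": "identity", "coef": -0.2698, "center": 1.3, "scale": 0.5},
    {"name": "age:current_smoker", "transform": "identity", "coef": -0.0755, "center": [60, null], "scale": [5, null]},
    {"name": "age:systolic_bp", "transform": "identity", "coef": -0.0255, "center": [60, 120], "scale": [5, 20]},
    {"name": "age:total_chol", "transform": "identity", "coef": -0.0281, "center": [60, 6], "scale": [5, 1]},
    {"name": "age:hdl_chol", "transform": "identity", "coef": 0.0426, "center": [60, 1.3], "scale": [5, 0.5]}
  ],
  "mean_lp": 0,
  "baseline_survival_10y": 0.9605,
  "source": "SCORE2 risk model for men, uncalibrated log hazard ratios and baseline survival (SCORE2 working group, 2021, supplementary methods)"
}
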