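{
  "model": "pce_aa",
  "stratum": {"sex": "female", "group": "African American"},
  "units": {"chol": "mg/dL", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "ln", "coef": 17.114},
    {"name": "total_chol", "transform": "ln", "coef": 0.940},
    {"name": "hdl_chol", "transform": "ln", "coef": -18.920},
    {"name": "age:hdl_chol", "transform": "ln", "coef": 4.475},
    {"name": "systolic_bp:on_bp_treatment", "transform": "ln", "coef": 29.291},
    {"name": "age:systolic_bp:on_bp_treatment", "transform": "ln", "coef": -6.432},
    {"name": "systolic_bp:off_bp_treatment", "transform": "ln", "coef": 27.820},
    {"name": "age:systolic_bp:off_bp_treatment", "transform": "ln", "coef": -6.087},
    {"name": "current_smoker", "transform": "identity", "coef": 0.691},
    {"name": "diabetes", "transform": "identity", "coef": 0.874}
  ],
  "mean_lp": 86.61,
  "baseline_survival_10y": 0.9533,
  "source": "Pooled Cohort Equations, African American women (ACC/AHA 2013 guideline, Appendix 7)"
}
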