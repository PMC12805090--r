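{
  "model": "pce_aa",
  "stratum": {"sex": "male", "group": "African American"},
  "units": {"chol": "mg/dL", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "ln", "coef": 2.469},
    {"name": "total_chol", "transform": "ln", "coef": 0.302},
    {"name": "hdl_chol", "transform": "ln", "coef": -0.307},
    {"name": "systolic_bp:on_bp_treatment", "transform": "ln", "coef": 1.916},
    {"name": "systolic_bp:off_bp_treatment", "transform": "ln", "coef": 1.809},
    {"name": "current_smoker", "transform": "identity", "coef": 0.549},
    {"name": "diabetes", "transform": "identity", "coef": 0.645}
  ],
  "mean_lp": 19.54,
  "baseline_survival_10y": 0.8954,
  "source": "Pooled Cohort Equations, African American men (ACC/AHA 2013 guideline, Appendix 7)"
}
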