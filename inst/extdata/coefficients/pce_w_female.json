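{
  "model": "pce_w",
  "stratum": {"sex": "female", "group": "White"},
  "units": {"chol": "mg/dL", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "ln", "coef": -29.799},
    {"name": "age", "transform": "ln2", "coef": 4.884},
    {"name": "total_chol", "transform": "ln", "coef": 13.540},
    {"name": "age:total_chol", "transform": "ln", "coef": -3.114},
    {"name": "hdl_chol", "transform": "ln", "coef": -13.578},
    {"name": "age:hdl_chol", "transform": "ln", "coef": 3.149},
    {"name": "systolic_bp:on_bp_treatment", "transform": "ln", "coef": 2.019},
    {"name": "systolic_bp:off_bp_treatment", "transform": "ln", "coef": 1.957},
    {"name": "current_smoker", "transform": "identity", "coef": 7.574},
    {"name": "age:current_smoker", "transform": "ln", "coef": -1.665},
    {"name": "diabetes", "transform": "identity", "coef": 0.661}
  ],
  "mean_lp": -29.18,
  "baseline_survival_10y": 0.9665,
  "source": "Pooled Cohort Equations, non-Hispanic White women (ACC/AHA 2013 guideline, Appendix 7)"
}
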