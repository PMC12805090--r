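{
  "model": "pce_w",
  "stratum": {"sex": "male", "group": "White"},
  "units": {"chol": "mg/dL", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "ln", "coef": 12.344},
    {"name": "total_chol", "transform": "ln", "coef": 11.853},
    {"name": "age:total_chol", "transform": "ln", "coef": -2.664},
    {"name": "hdl_chol", "transform": "ln", "coef": -7.990},
    {"name": "age:hdl_chol", "transform": "ln", "coef": 1.769},
    {"name": "systolic_bp:on_bp_treatment", "transform": "ln", "coef": 1.797},
    {"name": "systolic_bp:off_bp_treatment", "transform": "ln", "coef": 1.764},
    {"name": "current_smoker", "transform": "identity", "coef": 7.837},
    {"name": "age:current_smoker", "transform": "ln", "coef": -1.795},
    {"name": "diabetes", "transform": "identity", "coef": 0.658}
  ],
  "mean_lp": 61.18,
  "baseline_survival_10y": 0.9144,
  "source": "Pooled Cohort Equations, non-Hispanic White men (ACC/AHA 2013 guideline, Appendix 7)"
}
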