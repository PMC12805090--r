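{
  "model": "frs_atp3",
  "stratum": {"sex": "male"},
  "units": {"chol": "mg/dL", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "ln", "coef": 52.00961},
    {"name": "total_chol", "transform": "ln", "coef": 20.014077},
    {"name": "age:total_chol", "transform": "ln", "coef": -4.605038},
    {"name": "hdl_chol", "transform": "ln", "coef": -0.905964},
    {"name": "systolic_bp", "transform": "ln", "coef": 1.305784},
    {"name": "on_bp_treatment", "transform": "identity", "coef": 0.241549},
    {"name": "current_smoker", "transform": "identity", "coef": 12.096316},
    {"name": "age:current_smoker", "transform": "ln", "coef": -2.84367, "cap": [70, null]},
    {"name": "age", "transform": "ln2", "coef": -2.93323}
  ],
  "mean_lp": 172.300168,
  "baseline_survival_10y": 0.9402,
  "source": "Framingham hard-CHD Cox model for men as used by the ATP III risk assessment tool (NCEP ATP III, 2002)"
}
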