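{
  "model": "frs_atp3",
  "stratum": {"sex": "female"},
  "units": {"chol": "mg/dL", "sbp": "mmHg"},
  "terms": [
    {"name": "age", "transform": "ln", "coef": 31.764001},
    {"name": "total_chol", "transform": "ln", "coef": 22.465206},
    {"name": "age:total_chol", "transform": "ln", "coef": -5.060998},
    {"name": "hdl_chol", "transform": "ln", "coef": -1.187731},
    {"name": "systolic_bp", "transform": "ln", "coef": 2.552905},
    {"name": "on_bp_treatment", "transform": "identity", "coef": 0.420251},
    {"name": "current_smoker", "transform": "identity", "coef": 13.07543},
    {"name": "age:current_smoker", "transform": "ln", "coef": -2.996945, "cap": [78, null]}
  ],
  "mean_lp": 146.5933061,
  "baseline_survival_10y": 0.98767,
  "source": "Framingham hard-CHD Cox model for women as used by the ATP III risk assessment tool (NCEP ATP III, 2002)"
}
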