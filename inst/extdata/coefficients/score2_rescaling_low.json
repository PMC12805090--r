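{
  "model": "score2",
  "region": "low",
  "strata": [
    {"sex": "male", "scale1": -0.5699, "scale2": 0.7476},
    {"sex": "female", "scale1": -0.7380, "scale2": 0.7019}
  ],
  "source": "SCORE2 low-risk-region rescaling factors (SCORE2 working group, 2021, supplementary table); shipped as the default low-risk factors and overridable via configuration"
}
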