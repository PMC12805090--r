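{
  "CHD": {
    "nonfatal": ["I21-I22"],
    "fatal": ["I20-I25"]
  },
  "ASCVD": {
    "nonfatal": ["I21-I22", "I60-I64"],
    "fatal": ["I20-I25", "I60-I63", "I67-I69"]
  },
  "CVD": {
    "nonfatal": ["I10-I16", "I20-I25", "I44-I50", "I60-I69", "I70"],
    "fatal": ["I10-I16", "I20-I25", "I44-I50", "I60-I69", "I70"]
  }
}
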