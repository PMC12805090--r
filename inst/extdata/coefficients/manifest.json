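{
  "frs_atp3_female.json": "042febb36674e55b2af1efa72f92bccf",
  "frs_atp3_male.json": "56c6fa00a9121d93be6a6719e9f93b06",
  "pce_aa_female.json": "44ebbd0ccc75a72b213c2fd9f47a2a3d",
  "pce_aa_male.json": "a5c39e6ea963cdcbcd70e2a463258395",
  "pce_w_female.json": "73f8c42d14ab4dd1401ea6d0b02eaf2e",
  "pce_w_male.json": "a7265f05c942969196f82869e5e35bc7",
  "score2_female.json": "ec09fc57848b4b6991099cf9f771f034",
  "score2_male.json": "d0985d77e89c665569414aa5c6190f0e",
  "score2_rescaling_low.json": "5e0a185d97eb5916c82eeae1cea22ee1"
}
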