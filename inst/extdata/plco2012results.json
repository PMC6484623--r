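{
  "intercept": -4.43538,
  "beta_group": {
    "group2": 0.6554117,
    "group3": 0.9798233,
    "group4": 2.194061
  },
  "beta_fp": -0.2713125,
  "fp_power": -0.5,
  "centering": 7.045149954
}
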