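{
  "_comment": "SYNTHETIC demonstration base-risk model. These are NOT the published PLCOm2012 coefficients (which are distributed with the original model); they exist only to exercise the pluggable base-model schema.",
  "intercept": -5.0,
  "terms": [
    {
      "covariate": "age",
      "transform": "identity",
      "coefficient": 0.08,
      "center": 62
    },
    {
      "covariate": "smoking_duration",
      "transform": "identity",
      "coefficient": 0.03,
      "center": 27
    },
    {
      "covariate": "smoking_status",
      "transform": "indicator",
      "level": "current",
      "coefficient": 0.4
    }
  ]
}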