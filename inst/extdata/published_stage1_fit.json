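{
  "predictor_names": ["parental_concerns", "no_two_word", "vocab_count"],
  "coefficients": {
    "(Intercept)": -1.217,
    "parental_concerns": 1.231,
    "no_two_word": 1.268,
    "vocab_count": -0.088
  },
  "standard_errors": {
    "(Intercept)": 0.777,
    "parental_concerns": 0.353,
    "no_two_word": 0.472,
    "vocab_count": 0.016
  },
  "log_likelihood": null,
  "null_log_likelihood": null,
  "n": 621,
  "converged": true
}
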