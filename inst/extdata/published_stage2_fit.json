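{
  "predictor_names": ["parental_concerns", "no_two_word", "vocab_count", "word_comprehension"],
  "coefficients": {
    "(Intercept)": -0.069,
    "parental_concerns": 0.721,
    "no_two_word": 1.159,
    "vocab_count": -0.038,
    "word_comprehension": -0.284
  },
  "standard_errors": {
    "(Intercept)": 0.882,
    "parental_concerns": 0.352,
    "no_two_word": 0.448,
    "vocab_count": 0.018,
    "word_comprehension": 0.084
  },
  "log_likelihood": null,
  "null_log_likelihood": null,
  "n": 224,
  "converged": true
}
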