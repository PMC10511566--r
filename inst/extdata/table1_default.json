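{
  "age_mean": 46.99,
  "age_sd": 14.61,
  "age_range": [18, 86],
  "edu_mean": 14.66,
  "edu_sd": 3.27,
  "edu_range": [1, 24],
  "p_female": 0.605,
  "lang_probs": {
    "EN": 0.553, "DE": 0.196, "ES": 0.092, "IT": 0.073, "PL": 0.030,
    "FRCA": 0.021, "FR": 0.006, "NL": 0.014, "ESLA": 0.009, "DA": 0.006
  },
  "hand_probs": {"r": 0.898, "l": 0.077, "mixed": 0.025}
}
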