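{
  "version": "0.1-synthetic",
  "note": "Entirely synthetic Cox-score coefficient tables for testing the table-driven 10-year risk engine. These are NOT the published China-PAR coefficients; supply those separately in the same schema.",
  "tables": [
    {
      "sex": "female",
      "S0": 0.945,
      "terms": [
        {"term": "age",            "variables": "age",              "transform": "identity",  "coef": 0.070, "mean": 55.90},
        {"term": "wc",             "variables": "wc",               "transform": "identity",  "coef": 0.020, "mean": 84.23},
        {"term": "sbp",            "variables": "sbp",              "transform": "identity",  "coef": 0.018, "mean": 125.57},
        {"term": "sbp_treated",    "variables": "sbp * bp_treated", "transform": "identity",  "coef": 0.002, "mean": 17.59},
        {"term": "log_tc",         "variables": "tc",               "transform": "log",       "coef": 0.350, "mean": 5.219},
        {"term": "log_hdl",        "variables": "hdl",              "transform": "log",       "coef": -0.500, "mean": 3.938},
        {"term": "smoking_current","variables": "smoking=current",  "transform": "indicator", "coef": 0.400, "mean": 0.196},
        {"term": "diabetes",       "variables": "diabetes",         "transform": "indicator", "coef": 0.500, "mean": 0.091},
        {"term": "family_history", "variables": "family_history",   "transform": "indicator", "coef": 0.300, "mean": 0.153}
      ]
    },
    {
      "sex": "male",
      "S0": 0.920,
      "terms": [
        {"term": "age",            "variables": "age",              "transform": "identity",  "coef": 0.060, "mean": 55.90},
        {"term": "wc",             "variables": "wc",               "transform": "identity",  "coef": 0.022, "mean": 84.23},
        {"term": "sbp",            "variables": "sbp",              "transform": "identity",  "coef": 0.016, "mean": 125.57},
        {"term": "sbp_treated",    "variables": "sbp * bp_treated", "transform": "identity",  "coef": 0.002, "mean": 17.59},
        {"term": "log_tc",         "variables": "tc",               "transform": "log",       "coef": 0.300, "mean": 5.219},
        {"term": "log_hdl",        "variables": "hdl",              "transform": "log",       "coef": -0.450, "mean": 3.938},
        {"term": "smoking_current","variables": "smoking=current",  "transform": "indicator", "coef": 0.450, "mean": 0.196},
        {"term": "diabetes",       "variables": "diabetes",         "transform": "indicator", "coef": 0.480, "mean": 0.091},
        {"term": "family_history", "variables": "family_history",   "transform": "indicator", "coef": 0.320, "mean": 0.153}
      ]
    }
  ]
}
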