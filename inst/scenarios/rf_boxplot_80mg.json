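{
  "name": "rf_boxplot_80mg",
  "seed": 42,
  "outputs": ["box", "nca"],
  "groups": [
    {
      "label": "healthy",
      "population": {
        "n": 100,
        "health_state": "healthy",
        "age_range": [18, 74],
        "female_fraction": 0.25
      },
      "regimen": {
        "route": "oral",
        "amount_mg": 80,
        "interval_h": 24,
        "n_doses": 7
      }
    },
    {
      "label": "moderate_rf",
      "population": {
        "n": 100,
        "health_state": "moderate_rf",
        "age_range": [18, 74],
        "female_fraction": 0.25
      },
      "regimen": {
        "route": "oral",
        "amount_mg": 80,
        "interval_h": 24,
        "n_doses": 7
      }
    },
    {
      "label": "severe_rf",
      "population": {
        "n": 100,
        "health_state": "severe_rf",
        "age_range": [18, 74],
        "female_fraction": 0.25
      },
      "regimen": {
        "route": "oral",
        "amount_mg": 80,
        "interval_h": 24,
        "n_doses": 7
      }
    }
  ]
}
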