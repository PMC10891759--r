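{
  "name": "pediatric_age_bands",
  "seed": 7,
  "outputs": ["box"],
  "groups": [
    {
      "label": "iv_infants",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [0.25, 1], "female_fraction": 0.5},
      "regimen": {"route": "iv_bolus", "amount_mg": 0.32, "duration_h": 72}
    },
    {
      "label": "iv_toddlers",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [2, 4], "female_fraction": 0.5},
      "regimen": {"route": "iv_bolus", "amount_mg": 0.32, "duration_h": 72}
    },
    {
      "label": "iv_middle_childhood",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [6, 11], "female_fraction": 0.5},
      "regimen": {"route": "iv_bolus", "amount_mg": 0.32, "duration_h": 72}
    },
    {
      "label": "iv_young_teens",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [12, 14], "female_fraction": 0.5},
      "regimen": {"route": "iv_bolus", "amount_mg": 0.32, "duration_h": 72}
    },
    {
      "label": "iv_teenagers",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [15, 17], "female_fraction": 0.5},
      "regimen": {"route": "iv_bolus", "amount_mg": 0.32, "duration_h": 72}
    },
    {
      "label": "oral_infants",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [0.25, 1], "female_fraction": 0.5},
      "regimen": {"route": "oral", "amount_mg": 5, "duration_h": 96}
    },
    {
      "label": "oral_toddlers",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [2, 4], "female_fraction": 0.5},
      "regimen": {"route": "oral", "amount_mg": 5, "duration_h": 96}
    },
    {
      "label": "oral_middle_childhood",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [6, 11], "female_fraction": 0.5},
      "regimen": {"route": "oral", "amount_mg": 5, "duration_h": 96}
    },
    {
      "label": "oral_young_teens",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [12, 14], "female_fraction": 0.5},
      "regimen": {"route": "oral", "amount_mg": 5, "duration_h": 96}
    },
    {
      "label": "oral_teenagers",
      "population": {"n": 100, "health_state": "pediatric", "age_range": [15, 17], "female_fraction": 0.5},
      "regimen": {"route": "oral", "amount_mg": 5, "duration_h": 96}
    }
  ]
}
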