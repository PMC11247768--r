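{
  "name": "Cystic Fibrosis",
  "orpha_code": "586",
  "prevalence_denominator": 10311,
  "race_percent": {
    "African-American": 3.50,
    "European-American": 91.40,
    "Others": 5.10
  },
  "sex_percent": {
    "male": 51.70,
    "female": 49.30
  },
  "diagnosis": {
    "unit": "days",
    "low": 2,
    "high": 3,
    "mu": 2.5,
    "spread": 0.5
  },
  "death_rate_per_100k": {
    "<5": 6.23,
    "5-14": 12.46,
    "15-19": 40.50,
    "20-24": 71.65,
    "25-39": 280.37,
    "40-60": 190.03,
    ">60": 121.50
  },
  "clinical_params": [
    {
      "name": "chloride_level",
      "unit": "mmol/L",
      "low": 30.0,
      "high": 118.6,
      "mu": 74.3,
      "spread": 44.3
    }
  ]
}
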