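{
  "name": "Duchenne Muscular Dystrophy",
  "orpha_code": "98896",
  "prevalence_denominator": 6000,
  "race_percent": {
    "African-American": 29.00,
    "European-American": 43.00,
    "Others": 28.00
  },
  "sex_percent": {
    "male": 99.99,
    "female": 0.01
  },
  "diagnosis": {
    "unit": "years",
    "low": 1,
    "high": 3,
    "mu": 2,
    "spread": 1
  },
  "death_rate_per_100k": {
    "<5": 200,
    "5-14": 200,
    "15-19": 200,
    "20-24": 40500,
    "25-39": 73900,
    "40-60": 86700,
    ">60": 99990
  },
  "clinical_params": [
    {
      "name": "creatine_kinase",
      "unit": "units/L",
      "low": 350,
      "high": 23200,
      "mu": 11775,
      "spread": 6475
    }
  ]
}
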