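[
  {
    "endpoint": "xerostomia_mod_severe",
    "grade": "grade2",
    "provenance": "SYNTHETIC example coefficients for testing and demonstration only; placeholder values with plausible signs/magnitudes, NOT a validated clinical model.",
    "intercept": -2.4,
    "dose_terms": [
      {"structure": "parotid_L", "coefficient": 0.18, "transform": "sqrt"},
      {"structure": "parotid_R", "coefficient": 0.18, "transform": "sqrt"},
      {"structure": "submandibular_L", "coefficient": 0.012, "transform": "identity"},
      {"structure": "submandibular_R", "coefficient": 0.012, "transform": "identity"}
    ],
    "factor_terms": {
      "baseline_xerostomia": {"none_a_bit": 0.0, "moderate_severe": 0.9}
    }
  },
  {
    "endpoint": "dysphagia_ge2",
    "grade": "grade2",
    "provenance": "SYNTHETIC example coefficients for testing and demonstration only; placeholder values, NOT a validated clinical model.",
    "intercept": -3.0,
    "dose_terms": [
      {"structure": "oral_cavity", "coefficient": 0.028, "transform": "identity"},
      {"structure": "PCM_superior", "coefficient": 0.030, "transform": "identity"},
      {"structure": "PCM_medius", "coefficient": 0.016, "transform": "identity"}
    ],
    "factor_terms": {
      "baseline_dysphagia": {"grade_0_1": 0.0, "grade_2_3": 0.8}
    }
  },
  {
    "endpoint": "tube_feeding_dependence",
    "grade": "grade3_4",
    "provenance": "SYNTHETIC example coefficients for testing and demonstration only; placeholder values, NOT a validated clinical model.",
    "intercept": -4.3,
    "dose_terms": [
      {"structure": "PCM_inferior", "coefficient": 0.026, "transform": "identity"},
      {"structure": "PCM_medius", "coefficient": 0.010, "transform": "identity"},
      {"structure": "cricopharyngeal", "coefficient": 0.016, "transform": "identity"}
    ],
    "factor_terms": {
      "weight_loss": {"none": 0.0, "upto_10pct": 0.5, "over_10pct": 0.9},
      "modality": {"chemoradiation": 0.6, "conventional": 0.0, "accelerated": 0.4}
    }
  }
]
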