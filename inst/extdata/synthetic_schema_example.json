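[
  {
    "name": "age_years",
    "kind": "continuous"
  },
  {
    "name": "bmi",
    "kind": "continuous"
  },
  {
    "name": "total_chol",
    "kind": "continuous"
  },
  {
    "name": "ldl",
    "kind": "continuous"
  },
  {
    "name": "hdl",
    "kind": "continuous"
  },
  {
    "name": "triglycerides",
    "kind": "continuous"
  },
  {
    "name": "glucose",
    "kind": "continuous"
  },
  {
    "name": "creatinine",
    "kind": "continuous"
  },
  {
    "name": "systolic_bp",
    "kind": "continuous"
  },
  {
    "name": "crp",
    "kind": "continuous"
  },
  {
    "name": "gender_male",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "family_history",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "smoking_current",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "smoking_past",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "diabetes",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "dyslipidemia",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "hypertension",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "metabolic_syndrome",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "obesity",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  },
  {
    "name": "statins",
    "kind": "categorical",
    "categories": ["No", "Yes"]
  }
]
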