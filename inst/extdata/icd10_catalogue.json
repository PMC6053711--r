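[
  {
    "artefact_id": "icd_N30",
    "categories": [],
    "icd10_codes": [
      "N30"
    ],
    "sensitive": false,
    "text": "Urinary findings may be consistent with an inflammation of the bladder (cystitis). Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_N04",
    "categories": [],
    "icd10_codes": [
      "N04"
    ],
    "sensitive": false,
    "text": "The combination of findings may be consistent with a nephrotic syndrome pattern. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_N39",
    "categories": [],
    "icd10_codes": [
      "N39"
    ],
    "sensitive": false,
    "text": "Urinary findings may point to a disorder of the urinary system. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_N10",
    "categories": [],
    "icd10_codes": [
      "N10"
    ],
    "sensitive": false,
    "text": "Findings may be consistent with an acute kidney infection (pyelonephritis). Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_K75",
    "categories": [
      "HEPATITIS"
    ],
    "icd10_codes": [
      "K75"
    ],
    "sensitive": true,
    "text": "Liver markers may be consistent with an inflammatory liver disease, including hepatitis. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_K72",
    "categories": [
      "HEPATITIS"
    ],
    "icd10_codes": [
      "K72"
    ],
    "sensitive": true,
    "text": "Liver markers may be consistent with reduced liver function. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_K71",
    "categories": [
      "HEPATITIS"
    ],
    "icd10_codes": [
      "K71"
    ],
    "sensitive": true,
    "text": "Liver markers may be consistent with a toxic liver injury. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_K81",
    "categories": [],
    "icd10_codes": [
      "K81"
    ],
    "sensitive": false,
    "text": "Findings may be consistent with an inflammation of the gallbladder (cholecystitis). Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_K85",
    "categories": [],
    "icd10_codes": [
      "K85"
    ],
    "sensitive": false,
    "text": "Pancreatic enzyme findings may be consistent with acute pancreatitis. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_E05",
    "categories": [],
    "icd10_codes": [
      "E05"
    ],
    "sensitive": false,
    "text": "Thyroid markers may be consistent with an overactive thyroid (thyrotoxicosis). Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_E03",
    "categories": [],
    "icd10_codes": [
      "E03"
    ],
    "sensitive": false,
    "text": "Thyroid markers may be consistent with an underactive thyroid (hypothyroidism). Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_D50",
    "categories": [],
    "icd10_codes": [
      "D50"
    ],
    "sensitive": false,
    "text": "Red blood cell findings may be consistent with iron deficiency anemia. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_D72",
    "categories": [],
    "icd10_codes": [
      "D72"
    ],
    "sensitive": false,
    "text": "White blood cell findings may point to a disorder of the white blood cells. Please discuss this result with your physician."
  },
  {
    "artefact_id": "icd_N41",
    "categories": [],
    "icd10_codes": [
      "N41"
    ],
    "sensitive": false,
    "text": "Findings may be consistent with an inflammatory disease of the prostate. Please discuss this result with your physician."
  }
]
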