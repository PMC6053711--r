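{
  "artefacts": {
    "4784": {
      "artefact_id": "4784",
      "categories": [],
      "icd10_codes": [
        "R73.0"
      ],
      "sensitive": false,
      "text": "Fasting plasma glucose is mildly elevated while HbA1c remains below the diabetes range. This pattern may be consistent with impaired fasting glycemia (sometimes called prediabetes). Consider repeating the test and discussing lifestyle measures with your physician."
    },
    "4786": {
      "artefact_id": "4786",
      "categories": [],
      "icd10_codes": [
        "E11"
      ],
      "sensitive": false,
      "text": "Plasma glucose and HbA1c are both above their reference intervals while C-peptide is preserved. This combination may be consistent with type 2 diabetes mellitus. Please arrange a consultation with your physician to confirm the finding and plan further diagnostics."
    },
    "4788": {
      "artefact_id": "4788",
      "categories": [],
      "icd10_codes": [
        "E16.2"
      ],
      "sensitive": false,
      "text": "Plasma glucose is below its reference interval, which may indicate hypoglycaemia. If you experience dizziness, sweating or confusion, seek medical attention; otherwise discuss this result with your physician."
    },
    "4790": {
      "artefact_id": "4790",
      "categories": [],
      "icd10_codes": [],
      "sensitive": false,
      "text": "C-peptide is outside its reference interval, which can reflect altered insulin secretion. This finding is best interpreted together with your clinical history; please discuss it with your physician."
    }
  },
  "configurations": {
    "blood_sugar": {
      "direct_rule_ids": [
        "4783",
        "4787",
        "4785",
        "4789"
      ],
      "test_id": "blood_sugar"
    }
  },
  "exclusions": {
    "4795": {
      "exclusion_id": "4795",
      "expr": {
        "condition": {
          "component_code": "hb",
          "operand_high": 5,
          "operand_low": 0,
          "operator": "INCLUDES"
        },
        "kind": "LEAF"
      },
      "target_rule_ids": [
        "4785"
      ]
    }
  },
  "rules": {
    "4783": {
      "artefact_id": "4784",
      "author": "expert.ivanova",
      "expr": {
        "children": [
          {
            "condition": {
              "component_code": "glucose",
              "operand_high": 6.9,
              "operand_low": 6.3,
              "operator": "INCLUDES"
            },
            "kind": "LEAF"
          },
          {
            "condition": {
              "component_code": "hba1c_pct",
              "operand_high": 6.4,
              "operand_low": 4,
              "operator": "INCLUDES"
            },
            "kind": "LEAF"
          }
        ],
        "kind": "AND"
      },
      "reviewer": "expert.petrov",
      "rule_id": "4783",
      "status": "PRODUCTION",
      "test_id": "blood_sugar"
    },
    "4785": {
      "artefact_id": "4786",
      "author": "expert.ivanova",
      "expr": {
        "children": [
          {
            "condition": {
              "component_code": "glucose",
              "operand_high": 6.9,
              "operand_low": 0,
              "operator": "EXCLUDES"
            },
            "kind": "LEAF"
          },
          {
            "condition": {
              "component_code": "hba1c_pct",
              "operand_high": 6.4,
              "operand_low": 0,
              "operator": "EXCLUDES"
            },
            "kind": "LEAF"
          },
          {
            "condition": {
              "component_code": "hba1c_mmolmol",
              "operand_high": 46,
              "operand_low": 0,
              "operator": "EXCLUDES"
            },
            "kind": "LEAF"
          },
          {
            "condition": {
              "component_code": "c_peptide",
              "operand_high": 1730,
              "operand_low": 260,
              "operator": "INCLUDES"
            },
            "kind": "LEAF"
          }
        ],
        "kind": "AND"
      },
      "reviewer": "expert.petrov",
      "rule_id": "4785",
      "status": "PRODUCTION",
      "test_id": "blood_sugar"
    },
    "4787": {
      "artefact_id": "4788",
      "author": "expert.petrov",
      "expr": {
        "condition": {
          "component_code": "glucose",
          "operand_high": 3.9,
          "operand_low": 0,
          "operator": "INCLUDES"
        },
        "kind": "LEAF"
      },
      "reviewer": "expert.ivanova",
      "rule_id": "4787",
      "status": "PRODUCTION",
      "test_id": "blood_sugar"
    },
    "4789": {
      "artefact_id": "4790",
      "author": "expert.ivanova",
      "expr": {
        "condition": {
          "component_code": "c_peptide",
          "operand_high": 1730,
          "operand_low": 260,
          "operator": "EXCLUDES"
        },
        "kind": "LEAF"
      },
      "rule_id": "4789",
      "status": "DRAFT",
      "test_id": "blood_sugar"
    }
  },
  "tests": {
    "blood_sugar": {
      "components": [
        {
          "code": "hba1c_mmolmol",
          "name": "Concentration of HbA1C",
          "reference_high": 42,
          "reference_low": 20,
          "unit": "mmol/mol"
        },
        {
          "code": "hba1c_pct",
          "name": "Concentration of HbA1C",
          "reference_high": 6,
          "reference_low": 4,
          "unit": "%"
        },
        {
          "code": "hb",
          "name": "Concentration of Hb",
          "reference_high": 10.9,
          "reference_low": 7.4,
          "unit": "mmol/L"
        },
        {
          "code": "glucose",
          "name": "Concentration of Glucose in Plasma",
          "reference_high": 6.2,
          "reference_low": 4,
          "unit": "mmol/L"
        },
        {
          "code": "c_peptide",
          "name": "Concentration of C-Peptide",
          "reference_high": 1730,
          "reference_low": 260,
          "unit": "pmol/L"
        }
      ],
      "name": "Blood Sugar Test",
      "test_id": "blood_sugar"
    }
  },
  "version": "1.0"
}
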