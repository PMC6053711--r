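{
  "observations": [
    {
      "component_code": "hba1c_mmolmol",
      "observed_at": "2024-03-02T08:15:00Z",
      "unit": "mmol/mol",
      "value": 53
    },
    {
      "component_code": "hba1c_pct",
      "observed_at": "2024-03-02T08:15:00Z",
      "unit": "%",
      "value": 7
    },
    {
      "component_code": "hb",
      "observed_at": "2024-03-02T08:15:00Z",
      "unit": "mmol/L",
      "value": 9
    },
    {
      "component_code": "glucose",
      "observed_at": "2024-03-02T08:15:00Z",
      "unit": "mmol/L",
      "value": 7.8
    },
    {
      "component_code": "c_peptide",
      "observed_at": "2024-03-02T08:15:00Z",
      "unit": "pmol/L",
      "value": 900
    }
  ],
  "order_id": "ord-2024-0001",
  "ordered_test_ids": [
    "blood_sugar"
  ],
  "patient": {
    "birth_date": "1968-05-12",
    "patient_id": "patient-001",
    "sex": "FEMALE"
  }
}
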