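{
  "components": [
    {
      "code": "wbc",
      "name": "White blood cells",
      "reference_high": 11,
      "reference_low": 4,
      "unit": "10^9/L"
    },
    {
      "code": "rbc",
      "name": "Red blood cells",
      "reference_high": 5.8,
      "reference_low": 3.8,
      "unit": "10^12/L"
    },
    {
      "code": "hgb",
      "name": "Hemoglobin",
      "reference_high": 170,
      "reference_low": 120,
      "unit": "g/L"
    },
    {
      "code": "hct",
      "name": "Hematocrit",
      "reference_high": 50,
      "reference_low": 36,
      "unit": "%"
    },
    {
      "code": "mcv",
      "name": "Mean corpuscular volume",
      "reference_high": 100,
      "reference_low": 80,
      "unit": "fL"
    },
    {
      "code": "mch",
      "name": "Mean corpuscular hemoglobin",
      "reference_high": 34,
      "reference_low": 27,
      "unit": "pg"
    },
    {
      "code": "mchc",
      "name": "Mean corpuscular hemoglobin concentration",
      "reference_high": 360,
      "reference_low": 320,
      "unit": "g/L"
    },
    {
      "code": "rdw",
      "name": "Red cell distribution width",
      "reference_high": 14.5,
      "reference_low": 11.5,
      "unit": "%"
    },
    {
      "code": "plt",
      "name": "Platelets",
      "reference_high": 400,
      "reference_low": 150,
      "unit": "10^9/L"
    },
    {
      "code": "mpv",
      "name": "Mean platelet volume",
      "reference_high": 11.5,
      "reference_low": 7.5,
      "unit": "fL"
    },
    {
      "code": "pdw",
      "name": "Platelet distribution width",
      "reference_high": 18,
      "reference_low": 10,
      "unit": "%"
    },
    {
      "code": "pct",
      "name": "Plateletcrit",
      "reference_high": 0.5,
      "reference_low": 0.1,
      "unit": "%"
    },
    {
      "code": "neut_abs",
      "name": "Neutrophils, absolute",
      "reference_high": 7.5,
      "reference_low": 2,
      "unit": "10^9/L"
    },
    {
      "code": "neut_pct",
      "name": "Neutrophils",
      "reference_high": 75,
      "reference_low": 40,
      "unit": "%"
    },
    {
      "code": "lymph_abs",
      "name": "Lymphocytes, absolute",
      "reference_high": 4,
      "reference_low": 1,
      "unit": "10^9/L"
    },
    {
      "code": "lymph_pct",
      "name": "Lymphocytes",
      "reference_high": 45,
      "reference_low": 20,
      "unit": "%"
    },
    {
      "code": "mono_abs",
      "name": "Monocytes, absolute",
      "reference_high": 1,
      "reference_low": 0.2,
      "unit": "10^9/L"
    },
    {
      "code": "mono_pct",
      "name": "Monocytes",
      "reference_high": 10,
      "reference_low": 2,
      "unit": "%"
    },
    {
      "code": "eos_abs",
      "name": "Eosinophils, absolute",
      "reference_high": 0.5,
      "reference_low": 0,
      "unit": "10^9/L"
    },
    {
      "code": "eos_pct",
      "name": "Eosinophils",
      "reference_high": 6,
      "reference_low": 0,
      "unit": "%"
    },
    {
      "code": "baso_abs",
      "name": "Basophils, absolute",
      "reference_high": 0.2,
      "reference_low": 0,
      "unit": "10^9/L"
    },
    {
      "code": "baso_pct",
      "name": "Basophils",
      "reference_high": 2,
      "reference_low": 0,
      "unit": "%"
    }
  ],
  "name": "Complete Blood Count",
  "test_id": "cbc"
}
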