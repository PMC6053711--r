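{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "labdss inference result",
  "type": "object",
  "required": ["order_id", "conclusions"],
  "properties": {
    "order_id": {"type": "string"},
    "evaluated_test_ids": {"type": "array", "items": {"type": "string"}},
    "conclusions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule_id", "artefact_id", "text"],
        "properties": {
          "rule_id": {"type": "string"},
          "artefact_id": {"type": "string"},
          "text": {"type": "string"},
          "icd10_codes": {"type": "array", "items": {"type": "string"}},
          "suppressed": {"type": "boolean"},
          "referral_notice": {"type": "string"}
        }
      }
    }
  }
}
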