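{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "labdss order bundle",
  "type": "object",
  "required": ["order_id", "patient", "observations"],
  "properties": {
    "order_id": {"type": "string", "minLength": 1},
    "patient": {
      "type": "object",
      "required": ["patient_id"],
      "properties": {
        "patient_id": {"type": "string", "minLength": 1},
        "sex": {"enum": ["MALE", "FEMALE", "UNKNOWN"]},
        "birth_date": {"type": "string", "format": "date"}
      }
    },
    "ordered_test_ids": {"type": "array", "items": {"type": "string"}},
    "observations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["component_code", "value", "unit"],
        "properties": {
          "component_code": {"type": "string", "minLength": 1},
          "value": {"type": "number"},
          "unit": {"type": "string", "minLength": 1},
          "observed_at": {"type": "string", "format": "date-time"}
        }
      }
    }
  }
}
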