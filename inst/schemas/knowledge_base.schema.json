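{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "labdss knowledge base",
  "type": "object",
  "required": ["version", "tests", "configurations", "rules", "exclusions", "artefacts"],
  "properties": {
    "version": {"type": "string"},
    "tests": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["test_id", "name", "components"],
        "properties": {
          "test_id": {"type": "string"},
          "name": {"type": "string"},
          "components": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["code", "name", "unit"],
              "properties": {
                "code": {"type": "string", "minLength": 1},
                "name": {"type": "string"},
                "unit": {"type": "string"},
                "reference_low": {"type": "number"},
                "reference_high": {"type": "number"}
              }
            }
          }
        }
      }
    },
    "configurations": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["test_id", "direct_rule_ids"],
        "properties": {
          "test_id": {"type": "string"},
          "direct_rule_ids": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "rules": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["rule_id", "test_id", "expr", "artefact_id", "status", "author"],
        "properties": {
          "rule_id": {"type": "string"},
          "test_id": {"type": "string"},
          "expr": {"$ref": "#/definitions/expr"},
          "artefact_id": {"type": "string"},
          "status": {"enum": ["DRAFT", "REVIEWED", "PRODUCTION"]},
          "author": {"type": "string"},
          "reviewer": {"type": "string"}
        }
      }
    },
    "exclusions": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["exclusion_id", "target_rule_ids", "expr"],
        "properties": {
          "exclusion_id": {"type": "string"},
          "target_rule_ids": {"type": "array", "minItems": 1, "items": {"type": "string"}},
          "expr": {"$ref": "#/definitions/expr"}
        }
      }
    },
    "artefacts": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["artefact_id", "text"],
        "properties": {
          "artefact_id": {"type": "string"},
          "text": {"type": "string", "minLength": 1},
          "icd10_codes": {
            "type": "array",
            "items": {"type": "string", "pattern": "^[A-Z][0-9]+(\\.[0-9]+)?$"}
          },
          "sensitive": {"type": "boolean"},
          "categories": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  },
  "definitions": {
    "expr": {
      "type": "object",
      "required": ["kind"],
      "oneOf": [
        {
          "properties": {
            "kind": {"const": "LEAF"},
            "condition": {
              "type": "object",
              "required": ["component_code", "operator"],
              "properties": {
                "component_code": {"type": "string"},
                "operator": {"enum": ["EQ", "NE", "INCLUDES", "EXCLUDES"]},
                "operand_low": {"type": "number"},
                "operand_high": {"type": "number"},
                "operand_eq": {"type": "number"}
              }
            }
          },
          "required": ["kind", "condition"]
        },
        {
          "properties": {
            "kind": {"enum": ["AND", "OR"]},
            "children": {"type": "array", "minItems": 2, "items": {"$ref": "#/definitions/expr"}}
          },
          "required": ["kind", "children"]
        },
        {
          "properties": {
            "kind": {"const": "NOT"},
            "children": {"type": "array", "minItems": 1, "maxItems": 1, "items": {"$ref": "#/definitions/expr"}}
          },
          "required": ["kind", "children"]
        }
      ]
    }
  }
}
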