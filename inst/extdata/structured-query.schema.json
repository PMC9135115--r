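{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/schemas/structured-query.json",
  "title": "Structured Query",
  "description": "Feasibility query: inclusion criteria in conjunctive normal form (outer list AND, inner list OR), exclusion criteria in disjunctive normal form (outer list OR, inner list AND).",
  "type": "object",
  "additionalProperties": false,
  "required": ["version", "inclusionCriteria"],
  "properties": {
    "version": { "type": "string", "minLength": 1 },
    "inclusionCriteria": {
      "type": "array", "minItems": 1,
      "items": { "$ref": "#/definitions/criterionGroup" }
    },
    "exclusionCriteria": {
      "type": "array",
      "items": { "$ref": "#/definitions/criterionGroup" }
    }
  },
  "definitions": {
    "criterionGroup": {
      "type": "array", "minItems": 1,
      "items": { "$ref": "#/definitions/criterion" }
    },
    "criterion": {
      "type": "object",
      "additionalProperties": false,
      "required": ["termCodes"],
      "properties": {
        "termCodes": {
          "type": "array", "minItems": 1,
          "items": { "$ref": "#/definitions/termCode" }
        },
        "valueFilter": { "$ref": "#/definitions/valueFilter" },
        "timeRestriction": { "$ref": "#/definitions/timeRestriction" }
      }
    },
    "termCode": {
      "type": "object",
      "additionalProperties": false,
      "required": ["system", "code"],
      "properties": {
        "system": { "type": "string", "minLength": 1 },
        "code": { "type": "string", "minLength": 1 },
        "display": { "type": "string" }
      }
    },
    "valueFilter": {
      "oneOf": [
        {
          "type": "object",
          "additionalProperties": false,
          "required": ["type", "selectedConcepts"],
          "properties": {
            "type": { "const": "concept" },
            "selectedConcepts": {
              "type": "array", "minItems": 1,
              "items": { "$ref": "#/definitions/termCode" }
            }
          }
        },
        {
          "type": "object",
          "additionalProperties": false,
          "required": ["type", "comparator", "value", "unit"],
          "properties": {
            "type": { "const": "quantity-comparator" },
            "comparator": { "enum": ["gt", "ge", "lt", "le", "eq"] },
            "value": { "type": "number" },
            "unit": { "type": "string", "minLength": 1 }
          }
        },
        {
          "type": "object",
          "additionalProperties": false,
          "required": ["type", "minValue", "maxValue", "unit"],
          "properties": {
            "type": { "const": "quantity-range" },
            "minValue": { "type": "number" },
            "maxValue": { "type": "number" },
            "unit": { "type": "string", "minLength": 1 }
          }
        }
      ]
    },
    "timeRestriction": {
      "type": "object",
      "additionalProperties": false,
      "minProperties": 1,
      "properties": {
        "afterDate": { "type": "string", "format": "date" },
        "beforeDate": { "type": "string", "format": "date" }
      }
    }
  }
}
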