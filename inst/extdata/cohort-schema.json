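{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pimscreen cohort interchange format",
  "type": "object",
  "required": ["patients"],
  "properties": {
    "metadata": {
      "type": "object",
      "properties": {
        "source": {"type": "string"},
        "seed": {"type": "integer"}
      }
    },
    "patients": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["patient_id", "age_years", "sex", "medications"],
        "properties": {
          "patient_id": {"type": "string"},
          "age_years": {"type": "integer", "minimum": 60},
          "sex": {"enum": ["male", "female"]},
          "conditions": {
            "type": "array",
            "items": {"type": "string"},
            "description": "codes from the packaged condition vocabulary"
          },
          "labs": {
            "type": "object",
            "description": "absent keys mean the value was not measured; fixed units per field",
            "properties": {
              "egfr": {"type": "number", "exclusiveMinimum": 0, "description": "mL/min/1.73m2"},
              "serum_k": {"type": "number", "exclusiveMinimum": 0, "description": "mmol/L"},
              "serum_na": {"type": "number", "exclusiveMinimum": 0, "description": "mmol/L"},
              "corrected_ca": {"type": "number", "exclusiveMinimum": 0, "description": "mmol/L"},
              "systolic_bp": {"type": "number", "exclusiveMinimum": 0, "description": "mmHg"},
              "diastolic_bp": {"type": "number", "exclusiveMinimum": 0, "description": "mmHg"},
              "heart_rate": {"type": "number", "exclusiveMinimum": 0, "description": "beats/min"},
              "qtc_ms": {"type": "number", "exclusiveMinimum": 0, "description": "msec"},
              "po2_kpa": {"type": "number", "exclusiveMinimum": 0, "description": "kPa"},
              "pco2_kpa": {"type": "number", "exclusiveMinimum": 0, "description": "kPa"},
              "tsh_mu_l": {"type": "number", "exclusiveMinimum": 0, "description": "mU/L"},
              "bmi": {"type": "number", "exclusiveMinimum": 0, "description": "kg/m2"},
              "free_t4_status": {"enum": ["low", "normal", "high"]}
            }
          },
          "medications": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["atc_code"],
              "properties": {
                "atc_code": {"type": "string", "pattern": "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"},
                "name": {"type": "string"},
                "daily_dose": {"type": "number", "minimum": 0},
                "dose_unit": {"enum": ["mg", "ug", "g"]},
                "route": {"enum": ["oral", "parenteral", "topical", "transdermal", "inhaled", "other"]},
                "prn": {"type": "boolean"},
                "duration_days": {"type": "integer", "minimum": 0},
                "indication_code": {"type": "string"},
                "first_line": {"type": ["boolean", "null"]}
              }
            }
          }
        }
      }
    }
  }
}
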