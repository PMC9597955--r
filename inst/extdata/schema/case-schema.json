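{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "discordant_case",
  "description": "One discordant-review case: a question plus >= 2 competing systematic reviews with meta-analysis and recorded human judgments.",
  "type": "object",
  "required": ["case_id", "question", "reviews"],
  "properties": {
    "case_id": {"type": "string", "minLength": 1},
    "question": {"$ref": "#/$defs/pico_frame"},
    "primary_outcome": {"type": "string"},
    "primary_intervention": {"type": "string"},
    "reviews": {
      "type": "array",
      "minItems": 2,
      "items": {"$ref": "#/$defs/sr_record"}
    },
    "judged_same_question": {
      "type": "object",
      "additionalProperties": {"type": "boolean"},
      "description": "Map sr_id -> does this review address the case question (Step A). Missing ids default to true."
    },
    "judged_same_criteria": {
      "type": ["boolean", "null"],
      "description": "Recorded Step G judgment; null forces the computed PICO-term comparison."
    }
  },
  "$defs": {
    "yn_unknown": {"enum": ["yes", "no", "unknown"]},
    "pico_frame": {
      "type": "object",
      "required": ["intervention", "outcome"],
      "properties": {
        "population": {"type": "string"},
        "intervention": {"type": "string", "minLength": 1},
        "comparator": {"type": "string"},
        "outcome": {"type": "string", "minLength": 1},
        "population_terms": {"type": "array", "items": {"type": "string"}},
        "intervention_terms": {"type": "array", "items": {"type": "string"}},
        "comparator_terms": {"type": "array", "items": {"type": "string"}},
        "outcome_terms": {"type": "array", "items": {"type": "string"}}
      }
    },
    "search_profile": {
      "type": "object",
      "properties": {
        "databases": {"type": "array", "items": {"type": "string"}},
        "grey_literature": {"$ref": "#/$defs/yn_unknown"},
        "last_search_date": {
          "type": "string",
          "description": "ISO-8601 date or the literal 'unknown'"
        },
        "duplicate_independent_screening": {"$ref": "#/$defs/yn_unknown"},
        "language_restriction": {"enum": ["none", "restricted", "unknown"]},
        "publication_status_scope": {
          "enum": ["published_only", "includes_unpublished", "unknown"]
        },
        "ipd_analysis": {"enum": ["yes", "no"]}
      }
    },
    "quality_rating": {
      "type": "object",
      "required": ["tool", "raw_level"],
      "properties": {
        "tool": {"enum": ["AMSTAR", "AMSTAR2", "OXMAN_GUYATT", "ROBIS"]},
        "raw_level": {"type": "string"},
        "ordinal_rank": {"type": "integer"},
        "rct_quality_assessed": {"$ref": "#/$defs/yn_unknown"}
      }
    },
    "effect_estimate": {
      "type": "object",
      "required": ["measure", "point", "benefit_direction"],
      "properties": {
        "measure": {"enum": ["RR", "OR", "MD", "SMD"]},
        "point": {"type": "number"},
        "ci_low": {"type": ["number", "null"]},
        "ci_high": {"type": ["number", "null"]},
        "p_value": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
        "benefit_direction": {"enum": ["lower_better", "higher_better"]}
      }
    },
    "synthesis_profile": {
      "type": "object",
      "properties": {
        "data_extraction": {"enum": ["duplicate", "single", "unknown"]},
        "heterogeneity_assessed": {"$ref": "#/$defs/yn_unknown"},
        "synthesis_appropriate": {"$ref": "#/$defs/yn_unknown"}
      }
    },
    "sr_record": {
      "type": "object",
      "required": ["label", "pico"],
      "properties": {
        "sr_id": {"type": "string"},
        "label": {"type": "string", "minLength": 1},
        "is_cochrane": {"type": "boolean"},
        "pico": {"$ref": "#/$defs/pico_frame"},
        "trials": {
          "type": "array",
          "items": {"type": "string"},
          "description": "Trial labels; normalized to firstauthor-year identifiers on load"
        },
        "search": {"$ref": "#/$defs/search_profile"},
        "quality": {"type": "array", "items": {"$ref": "#/$defs/quality_rating"}},
        "effect": {
          "oneOf": [{"$ref": "#/$defs/effect_estimate"}, {"type": "null"}]
        },
        "robis_verdict": {"enum": ["low_risk", "high_risk", "unknown"]},
        "synthesis": {"$ref": "#/$defs/synthesis_profile"}
      }
    }
  }
}
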