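{
  "$comment": "Reference schema for eocburden config files (JSON or YAML). All keys optional; omitted keys fall back to package defaults. Validation is performed by validate_parameters().",
  "type": "object",
  "properties": {
    "seed": {"type": "integer", "description": "seed for the synthetic input-table generators"},
    "settings": {
      "type": "object",
      "properties": {
        "discount_rate_annual": {"type": "number", "minimum": 0, "default": 0.03},
        "medicine_cpi": {"type": "number", "minimum": 0, "default": 0.0077},
        "general_cpi": {"type": "number", "minimum": 0, "default": 0.0197},
        "productivity_growth": {"type": "number", "minimum": 0, "default": 0.01},
        "vat_drugs": {"type": "number", "minimum": 0, "default": 0.04},
        "drug_deduction_rate": {"type": "number", "minimum": 0, "default": 0.075},
        "base_year": {"type": "integer", "default": 2016},
        "horizon_years": {"type": "integer", "minimum": 1, "default": 10},
        "cycle_days": {"type": "number", "minimum": 1, "default": 21},
        "retirement_age": {"type": "number", "default": 65},
        "admin_cost_per_min": {"type": "number", "default": 0.32},
        "admin_prep_minutes": {"type": "number", "default": 30},
        "gfr_ml_min": {"type": "number", "default": 100},
        "informal_care_window": {"enum": ["post_progression", "last_48_days"]},
        "temp_leave_days_over": {"type": "number", "default": 70},
        "unit_cost_column": {"enum": ["unit_cost_min", "unit_cost", "unit_cost_max"]}
      }
    },
    "projection": {
      "type": "object",
      "properties": {
        "year1_oc": {"type": "number", "default": 3497},
        "annual_increment": {"type": "number", "default": 0},
        "epithelial_fraction": {"type": "number", "default": 0.9},
        "stage_counts_year1": {"type": "array", "items": {"type": "number"}},
        "integer_counts": {"type": "boolean", "default": true}
      }
    },
    "stages": {
      "type": "object",
      "description": "per-stage overrides keyed I/II/III/IV; fields as in default_stage_parameters()"
    },
    "care": {"type": "object"},
    "cascade": {"type": "object"},
    "palliative": {"type": "object"},
    "leave": {"type": "object"},
    "unit_costs_csv": {"type": "string"},
    "drug_catalogue_csv": {"type": "string"},
    "life_table_csv": {"type": "string"},
    "labour_csv": {"type": "string"}
  }
}
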