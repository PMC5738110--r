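{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fsflow metrics report",
  "type": "object",
  "required": ["report_type", "steps", "seed", "config"],
  "properties": {
    "report_type": {"enum": ["evaluation", "workflow"]},
    "steps": {"type": "array", "items": {"type": "string"}},
    "seed": {"type": "integer"},
    "config": {"type": "object"},
    "n_splits": {"type": "integer", "minimum": 2},
    "per_split_metrics": {"type": "array", "items": {"type": "object"}},
    "mean": {"type": "object"},
    "sd": {"type": "object"},
    "median_n_features": {"type": "number"},
    "train_fraction": {"type": "number"},
    "balance": {"enum": ["stratified", "downsample"]},
    "n_features_per_step": {"type": "object"},
    "final_feature_ids": {"type": "array", "items": {"type": "string"}},
    "training_metrics": {"type": "object"}
  },
  "allOf": [
    {
      "if": {"properties": {"report_type": {"const": "evaluation"}}},
      "then": {"required": ["n_splits", "per_split_metrics", "mean", "sd", "median_n_features"]}
    },
    {
      "if": {"properties": {"report_type": {"const": "workflow"}}},
      "then": {"required": ["n_features_per_step", "final_feature_ids"]}
    }
  ]
}
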