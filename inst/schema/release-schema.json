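{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "omp-annotation-release",
  "type": "object",
  "required": ["format", "genotypes", "annotations"],
  "properties": {
    "format": {"type": "string", "enum": ["omp-annotation-release"]},
    "genotypes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["genotype_id", "label", "genotype_text", "is_virtual"],
        "properties": {
          "genotype_id": {"type": "string", "pattern": "^OMP_ST:[0-9]+$"},
          "label": {"type": "string"},
          "genotype_text": {"type": "string"},
          "ancestry": {"type": ["string", "null"], "pattern": "^OMP_ST:[0-9]+$"},
          "source": {"type": ["string", "null"]},
          "reference": {"type": ["string", "null"]},
          "external_ids": {"type": "array", "items": {"type": "string"}},
          "is_virtual": {"type": "boolean"}
        }
      }
    },
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["annotation_id", "genotype_id", "omp_term_id", "eco_id",
                     "reference", "history"],
        "properties": {
          "annotation_id": {"type": "string", "pattern": "^OMP_AN:[0-9]+(-[A-Za-z0-9]+)?$"},
          "genotype_id": {"type": "string", "pattern": "^OMP_ST:[0-9]+$"},
          "conditions": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["key", "value"],
              "properties": {
                "key": {"type": "string",
                        "enum": ["ENVO", "temperature", "pH", "medium", "other"]},
                "value": {"type": "string"}
              }
            }
          },
          "omp_term_id": {"type": "string", "pattern": "^[A-Za-z_]+:[0-9]+$"},
          "extensions": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["relation_id", "target_ids"],
              "properties": {
                "relation_id": {"type": "string"},
                "target_ids": {"type": "array", "items": {"type": "string"}}
              }
            }
          },
          "relative_to": {"type": ["string", "null"]},
          "qualifier": {"type": ["string", "null"],
                        "enum": ["Not", "Same phenotype as reference strain",
                                 "Same phenotype as in reference condition", null]},
          "eco_id": {"type": "string", "pattern": "^ECO:[0-9]+$"},
          "reference": {"type": "string"},
          "history": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["timestamp", "editor", "action"],
              "properties": {
                "timestamp": {"type": "string"},
                "editor": {"type": "string"},
                "action": {"type": "string", "enum": ["created", "revised"]},
                "note": {"type": ["string", "null"]}
              }
            }
          },
          "notes": {"type": ["string", "null"]}
        }
      }
    }
  }
}
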