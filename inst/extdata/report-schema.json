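{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "driftr pipeline report",
  "type": "object",
  "required": ["query", "params", "compounds", "targets", "fragments"],
  "properties": {
    "query": {
      "type": "object",
      "required_fields": ["mol_id", "n_atoms"]
    },
    "params": {
      "type": "object",
      "required_fields": ["tc_min", "min_overlap", "k_conformers", "exclude_self", "seed"]
    },
    "compounds": {
      "type": "array",
      "required_fields": ["mol_id"]
    },
    "targets": {
      "type": "array",
      "required_fields": ["target_id", "score", "confidence", "n_assays", "rank"]
    },
    "fragments": {
      "type": "array",
      "required_fields": ["fragment_key", "count", "rank"]
    },
    "notices": {
      "type": "array"
    }
  }
}
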