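{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "pathneighbor-report/1",
  "title": "pathneighbor analysis report",
  "type": "object",
  "required": ["schema", "config", "query_terms", "resolved", "unresolved",
               "query", "neighbors", "displayed", "memberships",
               "enrichment"],
  "properties": {
    "schema": {"const": "pathneighbor-report/1"},
    "config": {
      "type": "object",
      "required": ["species", "mode", "overlap_mode", "mtc_method", "threshold"],
      "properties": {
        "species": {"type": "string"},
        "mode": {"enum": ["quick", "advanced"]},
        "source_filter": {"type": ["array", "null"], "items": {"type": "string"}},
        "evidence_filter": {"type": ["array", "null"], "items": {"type": "string"}},
        "overlap_mode": {"enum": ["displayed", "neighbors_only"]},
        "mtc_method": {"const": "benjamini_hochberg"},
        "threshold": {"type": "number", "exclusiveMinimum": 0, "maximum": 1}
      }
    },
    "query_terms": {"type": "array", "items": {"type": "string"}},
    "resolved": {
      "type": "object",
      "additionalProperties": {"type": "array", "items": {"type": "string"}}
    },
    "unresolved": {"type": "array", "items": {"type": "string"}},
    "query": {"type": "array", "items": {"type": "string"}},
    "neighbors": {"type": "array", "items": {"type": "string"}},
    "displayed": {"type": "array", "items": {"type": "string"}},
    "memberships": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["accession", "source_db", "pathway_name"],
        "properties": {
          "accession": {"type": "string"},
          "source_db": {"type": "string"},
          "pathway_name": {"type": "string"}
        }
      }
    },
    "subnetwork": {
      "type": ["object", "null"],
      "required": ["species", "nodes", "edges"],
      "properties": {
        "species": {"type": "string"},
        "nodes": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["accession", "display_name"],
            "properties": {
              "accession": {"type": "string"},
              "display_name": {"type": "string"}
            }
          }
        },
        "edges": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["a", "b", "sources", "evidence_types", "pubmed_ids"],
            "properties": {
              "a": {"type": "string"},
              "b": {"type": "string"},
              "sources": {"type": "array", "items": {"type": "string"}, "minItems": 1},
              "evidence_types": {
                "type": "array",
                "items": {"enum": ["small_scale_physical",
                                   "high_throughput_physical", "genetic"]},
                "minItems": 1
              },
              "pubmed_ids": {"type": "array", "items": {"type": "string"}}
            }
          }
        }
      }
    },
    "enrichment": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source_db", "pathway_name", "N", "n", "K", "M",
                     "p_raw", "p_adj", "significant"],
        "properties": {
          "source_db": {"type": "string"},
          "pathway_name": {"type": "string"},
          "N": {"type": "integer", "minimum": 0},
          "n": {"type": "integer", "minimum": 0},
          "K": {"type": "integer", "minimum": 1},
          "M": {"type": "integer", "minimum": 1},
          "p_raw": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
          "p_adj": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
          "significant": {"type": "boolean"}
        }
      }
    }
  }
}
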