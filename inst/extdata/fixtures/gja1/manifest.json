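{
  "species": "human",
  "query_term": "gja1",
  "query_accession": "GJA1",
  "n_edges": 10,
  "query_degree": 10,
  "n_neighbors": 10,
  "egf_mapk_direct_interactors": 6,
  "universe_size": 20200,
  "pathways": [
    "KEGG::EGF/MAPK",
    "KEGG::WNT"
  ]
}
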