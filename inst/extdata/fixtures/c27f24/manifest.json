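{
  "species": "worm",
  "query_term": "c27f2.4",
  "query_accession": "C27F2.4",
  "n_edges": 3,
  "query_degree": 3,
  "n_neighbors": 3,
  "neighbors_with_membership": 1,
  "universe_size": 20000,
  "pathways": [
    "SignaLink::WNT",
    "SignaLink::EGF/MAPK"
  ]
}
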