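{
  "species": "worm",
  "query_term": "cdc-25.1",
  "query_accession": "CDC-25.1",
  "n_edges": 9,
  "query_degree": 9,
  "n_neighbors": 9,
  "neighbors_with_membership": 6,
  "universe_size": 20000,
  "pathways": [
    "SignaLink::EGF/MAPK",
    "SignaLink::IGF",
    "SignaLink::Notch",
    "SignaLink::TGF",
    "SignaLink::WNT"
  ]
}
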