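{
  "similarity": {
    "nodes": ["relatedness", "mate", "foraging", "nest_distance", "tolerance", "acoustic_distance"],
    "edges": [
      {"from": "relatedness", "to": "mate"},
      {"from": "relatedness", "to": "nest_distance"},
      {"from": "nest_distance", "to": "foraging"},
      {"from": "mate", "to": "tolerance"},
      {"from": "nest_distance", "to": "tolerance"},
      {"from": "relatedness", "to": "acoustic_distance"},
      {"from": "mate", "to": "acoustic_distance"},
      {"from": "foraging", "to": "acoustic_distance"},
      {"from": "nest_distance", "to": "acoustic_distance"},
      {"from": "tolerance", "to": "acoustic_distance"}
    ]
  },
  "diversity": {
    "nodes": ["age", "sex", "chamber_size", "tree_size", "network_position", "diversity"],
    "edges": [
      {"from": "age", "to": "diversity"},
      {"from": "sex", "to": "diversity"},
      {"from": "age", "to": "chamber_size"},
      {"from": "sex", "to": "chamber_size"},
      {"from": "age", "to": "tree_size"},
      {"from": "sex", "to": "tree_size"},
      {"from": "chamber_size", "to": "tree_size"},
      {"from": "age", "to": "network_position"},
      {"from": "sex", "to": "network_position"},
      {"from": "chamber_size", "to": "diversity"},
      {"from": "tree_size", "to": "diversity"},
      {"from": "network_position", "to": "diversity"}
    ]
  },
  "information": {
    "nodes": ["age", "degree", "tree_size", "information"],
    "edges": [
      {"from": "age", "to": "degree"},
      {"from": "age", "to": "tree_size"},
      {"from": "tree_size", "to": "degree"},
      {"from": "age", "to": "information"},
      {"from": "degree", "to": "information"},
      {"from": "tree_size", "to": "information"}
    ]
  }
}
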