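[
  {"outcome": "similarity", "exposure": "mate", "kind": "direct",
   "adjustment": "relatedness,foraging,nest_distance,tolerance",
   "expectation": "more similar",
   "note": "full dyadic model: distance ~ mate + relatedness + foraging + nest_distance + tolerance"},
  {"outcome": "similarity", "exposure": "foraging", "kind": "direct",
   "adjustment": "mate,relatedness,nest_distance,tolerance",
   "expectation": "more similar",
   "note": "full dyadic model, foraging association (simple ratio index) as exposure"},
  {"outcome": "similarity", "exposure": "nest_distance", "kind": "direct",
   "adjustment": "mate,relatedness,foraging,tolerance",
   "expectation": "more similar when closer",
   "note": "full dyadic model, normalised nest distance as exposure"},
  {"outcome": "similarity", "exposure": "tolerance", "kind": "direct",
   "adjustment": "mate,relatedness,foraging,nest_distance",
   "expectation": "more similar",
   "note": "full dyadic model, binary tolerance/affiliative edge as exposure"},
  {"outcome": "similarity", "exposure": "relatedness", "kind": "direct",
   "adjustment": "mate,tolerance",
   "expectation": "more similar",
   "note": "reduced model: distance ~ relatedness + mate + tolerance"},
  {"outcome": "diversity", "exposure": "network_position", "kind": "total",
   "adjustment": "age,sex,tolerance,tree_size",
   "expectation": "more diverse",
   "note": "network position stands for degree/eigenvector/betweenness/versatility, one model each"},
  {"outcome": "diversity", "exposure": "age", "kind": "direct",
   "adjustment": "network_position,chamber_size,sex",
   "expectation": "less diverse",
   "note": "the single-letter S in this row's source denotes sex, not similarity"},
  {"outcome": "diversity", "exposure": "sex", "kind": "direct",
   "adjustment": "network_position,age,chamber_size,tree_size",
   "expectation": "none",
   "note": "female contrast on contact-call diversity"},
  {"outcome": "diversity", "exposure": "chamber_size", "kind": "total",
   "adjustment": "age,sex",
   "expectation": "more diverse",
   "note": "matches build_adjustment(chamber_size, diversity, diversity DAG, total) = {age, sex}"},
  {"outcome": "diversity", "exposure": "tree_size", "kind": "direct",
   "adjustment": "network_position,age,sex,chamber_size",
   "expectation": "more diverse",
   "note": "tree group size on contact-call diversity"},
  {"outcome": "repertoire_entropy", "exposure": "sex", "kind": "direct",
   "adjustment": "network_position,age,chamber_size,tree_size",
   "expectation": "none",
   "note": "entropy models mirror the diversity models; intercept prior normal(1,1)"},
  {"outcome": "repertoire_entropy", "exposure": "chamber_size", "kind": "total",
   "adjustment": "age,sex",
   "expectation": "more diverse",
   "note": "entropy models mirror the diversity models; intercept prior normal(1,1)"},
  {"outcome": "repertoire_entropy", "exposure": "tree_size", "kind": "direct",
   "adjustment": "network_position,age,sex,chamber_size",
   "expectation": "more diverse",
   "note": "entropy models mirror the diversity models; intercept prior normal(1,1)"},
  {"outcome": "information", "exposure": "degree", "kind": "total",
   "adjustment": "age,tree_size",
   "expectation": "more information",
   "note": "counts of amplitude-modulation peaks; information ~ degree + age + tree_size"},
  {"outcome": "information", "exposure": "tree_size", "kind": "direct",
   "adjustment": "degree,age",
   "expectation": "more information",
   "note": "degree mediates tree size, so the shared model estimates the direct effect"},
  {"outcome": "information", "exposure": "age", "kind": "direct",
   "adjustment": "degree,tree_size",
   "expectation": "none",
   "note": "degree and tree size mediate age in the information DAG"}
]
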