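{
  "title": "panclade pipeline report",
  "required": [
    {"path": "parameters/seed", "type": "number"},
    {"path": "parameters/references", "type": "any"},
    {"path": "parameters/pivot", "type": "string"},
    {"path": "parameters/outgroup", "type": "string"},
    {"path": "pav/counts", "type": "list"},
    {"path": "pav/counts/core", "type": "number"},
    {"path": "pav/counts/variable", "type": "number"},
    {"path": "pav/counts/specific", "type": "number"},
    {"path": "pav/counts/total", "type": "number"},
    {"path": "pav/accumulation", "type": "list"},
    {"path": "pav/genome_tree", "type": "string"},
    {"path": "synteny/per_genome", "type": "list"},
    {"path": "ancestor/n_cars", "type": "number"},
    {"path": "ancestor/cars", "type": "list"},
    {"path": "ancestor/rearrangements", "type": "list"},
    {"path": "svs/summary", "type": "list"},
    {"path": "hotspots/n_regions", "type": "number"},
    {"path": "phylo/tree", "type": "string"},
    {"path": "phylo/root_age", "type": "number"},
    {"path": "truth_comparison/family_rand_index", "type": "number"},
    {"path": "truth_comparison/sv_recall", "type": "number"},
    {"path": "truth_comparison/sv_precision", "type": "number"},
    {"path": "checksums/pav", "type": "string"}
  ]
}
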