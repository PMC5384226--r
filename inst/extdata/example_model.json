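{
  "id": "example",
  "compartments": {"c": "cytosol", "e": "extracellular"},
  "extracellular_tags": ["e"],
  "metabolites": [
    {"id": "glc_e", "name": "glucose", "compartment": "e", "formula": "C6H12O6"},
    {"id": "glc_c", "name": "glucose", "compartment": "c", "formula": "C6H12O6"},
    {"id": "pyr_c", "name": "pyruvate", "compartment": "c"},
    {"id": "lac_e", "name": "lactate", "compartment": "e"}
  ],
  "reactions": [
    {"id": "EX_glc_e", "name": "glucose exchange",
     "metabolites": {"glc_e": -1},
     "lower_bound": -10, "upper_bound": 0,
     "gene_reaction_rule": "", "objective_coefficient": 0},
    {"id": "GLCt", "name": "glucose transport",
     "metabolites": {"glc_e": -1, "glc_c": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "gT1 or gT2", "objective_coefficient": 0},
    {"id": "GLYC", "name": "glycolysis (lumped)",
     "metabolites": {"glc_c": -1, "pyr_c": 2},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "gG1 and gG2", "objective_coefficient": 1},
    {"id": "LDHt", "name": "lactate production and export",
     "metabolites": {"pyr_c": -1, "lac_e": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "", "objective_coefficient": 0},
    {"id": "EX_lac_e", "name": "lactate exchange",
     "metabolites": {"lac_e": -1},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "", "objective_coefficient": 0}
  ],
  "genes": [{"id": "gT1"}, {"id": "gT2"}, {"id": "gG1"}, {"id": "gG2"}]
}
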