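{
  "id": "TOY3",
  "compartments": {"c": "cytoplasm", "e": "extracellular space"},
  "metabolites": [
    {"id": "A_e", "name": "substrate A (extracellular)", "compartment": "e", "formula": "C", "charge": 0},
    {"id": "A_c", "name": "substrate A", "compartment": "c", "formula": "C", "charge": 0},
    {"id": "B_c", "name": "precursor B", "compartment": "c", "formula": "C", "charge": 0}
  ],
  "reactions": [
    {
      "id": "EX_A",
      "name": "exchange of A",
      "metabolites": {"A_e": -1},
      "lower_bound": -10, "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0,
      "annotation": {"provenance": "native"}
    },
    {
      "id": "At",
      "name": "uptake of A",
      "metabolites": {"A_e": -1, "A_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Transport",
      "objective_coefficient": 0,
      "annotation": {"provenance": "native"}
    },
    {
      "id": "R1",
      "name": "conversion A to B",
      "metabolites": {"A_c": -1, "B_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "g1",
      "subsystem": "Core",
      "objective_coefficient": 0,
      "annotation": {"provenance": "native"}
    },
    {
      "id": "BIO",
      "name": "biomass drain",
      "metabolites": {"B_c": -1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Biomass and maintenance functions",
      "objective_coefficient": 1,
      "annotation": {"provenance": "native", "pseudo": true}
    }
  ],
  "genes": [{"id": "g1", "name": "g1"}],
  "version": "1"
}
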