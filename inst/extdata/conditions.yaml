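# Experimental cases for nucleus pulposus PPI-network prioritization:
# five case networks (three secretome-based, two mass-spectrometry-based),
# each with a no-treatment baseline and cytokine-stimulation conditions.
# Secretome networks are seeded by the most expressed analyte; MS networks
# by 25 cellular mediators previously described in the nucleus pulposus.
ms_seeds: &ms_seeds
  [CX3CL1, IL6ST, IL1B, IL6, CXCL8, IL18, IL16, GDF5, OSM, CXCL2, GDF6,
   IL17D, CCL3, IL20, TGFB1, CCL5, PMP2, LIF, CCL7, TNF, IGF1, CCL2,
   VEGFA, CXCL3, CXCL1]

networks:
  trauma:
    dataset_kind: secretome
    phenotype: trauma
    seeds: [SERPINE1]
  degenerated:
    dataset_kind: secretome
    phenotype: degenerated
    seeds: [MMP2]
  explant:
    dataset_kind: secretome
    phenotype: explant
    seeds: [MMP2]
  young:
    dataset_kind: mass_spec
    phenotype: young
    seeds: *ms_seeds
  old:
    dataset_kind: mass_spec
    phenotype: old
    seeds: *ms_seeds

conditions:
  - {name: trauma_baseline,          network: trauma,      stimuli: []}
  - {name: trauma_il4,               network: trauma,      stimuli: [IL4]}
  - {name: trauma_il1b,              network: trauma,      stimuli: [IL4, IL1B]}
  - {name: degenerated_baseline,     network: degenerated, stimuli: []}
  - {name: degenerated_il4,          network: degenerated, stimuli: [IL4]}
  - {name: degenerated_il10,         network: degenerated, stimuli: [IL10]}
  - {name: degenerated_il1b,         network: degenerated, stimuli: [IL1B]}
  - {name: degenerated_il1b_il4,     network: degenerated, stimuli: [IL1B, IL4]}
  - {name: degenerated_il1b_il10,    network: degenerated, stimuli: [IL1B, IL10]}
  - {name: explant_baseline,         network: explant,     stimuli: []}
  - {name: explant_il4,              network: explant,     stimuli: [IL4]}
  - {name: explant_il1b,             network: explant,     stimuli: [IL1B]}
  - {name: explant_il10,             network: explant,     stimuli: [IL10]}
  - {name: explant_il1b_il4,         network: explant,     stimuli: [IL1B, IL4]}
  - {name: young_baseline,           network: young,       stimuli: []}
  - {name: young_il4,                network: young,       stimuli: [IL4]}
  - {name: young_il10,               network: young,       stimuli: [IL10]}
  - {name: old_baseline,             network: old,         stimuli: []}
  - {name: old_il4,                  network: old,         stimuli: [IL4]}
  - {name: old_il10,                 network: old,         stimuli: [IL10]}
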