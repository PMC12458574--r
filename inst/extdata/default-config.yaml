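levels:
- level_id: 1
  n_stimuli: 2
  dimensions:
    colour:
    - orange
    - blue
    shape:
    - round
    - star
  n_blocks: 2
  trials_per_block: 30
  shift_gap_min: 6
  shift_gap_max: 11
- level_id: 2
  n_stimuli: 2
  dimensions:
    colour:
    - orange
    - blue
    shape:
    - round
    - star
    hair:
    - hair
    - no-hair
  n_blocks: 2
  trials_per_block: 35
  shift_gap_min: 6
  shift_gap_max: 11
- level_id: 3
  n_stimuli: 3
  dimensions:
    colour:
    - orange
    - blue
    - green
    shape:
    - round
    - star
    - hexagon
    hair:
    - hair
    - no-hair
    - curly-hair
  n_blocks: 2
  trials_per_block: 35
  shift_gap_min: 6
  shift_gap_max: 11
seed: 1
cohort:
  delta_b: -12.0
  delta_w: 3.0
  n_per_group: 29
exclusion_mode: weighted
model_spec: joint
gc_variant: proportion
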