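# Settings catalogue for the simulation study: two outcomes (xerostomia,
# dysphagia), two predictor-set sizes per outcome, and a low/high collinearity
# variant of each. target_events / p gives the events-per-variable (EPV) of
# the setting; "_hi" marks the high-collinearity variants.
defaults:
  n_dev: 592
  n_val: 10000
  n_clinical: 3
settings:
  - name: A
    outcome: xerostomia
    collinearity: low
    p: 7
    block_sizes: [2, 2]
    within_block_r: 0.8
    between_block_r: 0.2
    target_median_vif: 5
    target_events: 161
    seed: 101
  - name: A_hi
    outcome: xerostomia
    collinearity: high
    p: 7
    block_sizes: [2, 2]
    within_block_r: 0.8
    between_block_r: 0.2
    target_median_vif: 43
    target_events: 161
    seed: 102
  - name: B
    outcome: xerostomia
    collinearity: low
    p: 19
    block_sizes: [8, 8]
    within_block_r: 0.9
    between_block_r: 0.3
    target_median_vif: 5
    target_events: 152
    seed: 103
  - name: B_hi
    outcome: xerostomia
    collinearity: high
    p: 19
    block_sizes: [8, 8]
    within_block_r: 0.9
    between_block_r: 0.3
    target_median_vif: 43
    target_events: 152
    seed: 104
  - name: C
    outcome: dysphagia
    collinearity: low
    p: 13
    block_sizes: [5, 5]
    within_block_r: 0.8
    between_block_r: 0.2
    target_median_vif: 7
    target_events: 78
    seed: 105
  - name: C_hi
    outcome: dysphagia
    collinearity: high
    p: 13
    block_sizes: [5, 5]
    within_block_r: 0.8
    between_block_r: 0.2
    target_median_vif: 43
    target_events: 78
    seed: 106
  - name: D
    outcome: dysphagia
    collinearity: low
    p: 43
    block_sizes: [20, 20]
    within_block_r: 0.9
    between_block_r: 0.3
    target_median_vif: 7
    target_events: 86
    seed: 107
  - name: D_hi
    outcome: dysphagia
    collinearity: high
    p: 43
    block_sizes: [20, 20]
    within_block_r: 0.9
    between_block_r: 0.3
    target_median_vif: 43
    target_events: 86
    seed: 108
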