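# Demo configuration for run_pipeline(): a small, fully synthetic
# walkthrough of every stage.  All randomness derives from `seed`.
seed: 42
out_dir: results/demo
alpha: 0.05

stages:
  simulate: true
  bouts: true
  calcium: true
  fos: true
  stats: true

simulate:
  n_per_group: 6
  groups:
    trained:                 # earns its rewards on FR1, presses in bouts
      schedule: FR1
      criterion_rewards: 30
      session_cap: 7200
      bout_rate: 1.2         # bouts per minute
      presses_per_bout_mean: 4
      within_bout_iri_mean: 1.2
      solitary_rate: 0.4     # solitary presses per minute
    yoked:                   # noncontingent VT60 deliveries, sparse pressing
      schedule: VT
      criterion_rewards: 30
      session_cap: 7200
      bout_rate: 0.15
      presses_per_bout_mean: 2.5
      within_bout_iri_mean: 1.5
      solitary_rate: 0.3

bouts:
  gap_threshold: 5           # seconds
  epoch_width: 5

calcium:
  n_rois: 25
  duration: 300              # seconds per condition
  k_sigma: 3
  conditions:                # planted event rates, events per minute
    post_magazine: 1.5
    post_acquisition: 3.5

fos:
  n_animals_per_group: 5
  k: 2                       # mutual-KNN neighbors
  rates:                     # planted c-Fos+ densities, cells per mm^3
    aDLS: {trained: 9000, yoked: 5000}
    aDMS: {trained: 5000, yoked: 5000}
    pDMS: {trained: 8000, yoked: 5000}
    pDLS: {trained: 5000, yoked: 5000}
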