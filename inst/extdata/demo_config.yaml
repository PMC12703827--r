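# Demo pipeline configuration: a small synthetic cohort with alpha-band
# interbrain coupling planted in the feedback ("F") condition only.
seed: 42
output_dir: null          # defaults to a temporary directory
stages: [simulate, isc, nbs, cortex]
bands: [alpha]
simulation:
  n_dyads: 8
  n_channels: 8
  fs: 500
  duration: 30            # seconds per trial
  band: alpha
  effect_pairs: [[1, 1], [1, 2], [2, 3], [2, 4], [3, 5], [3, 6]]
  kappa_effect: 8         # feedback condition: concentrated phase coupling
  kappa_null: 0           # no-feedback condition: independent phases
  lag: 0.7853981633974483 # pi/4 mean interbrain lag
  noise_sd: 1
  line_amp: 0.5
nbs:
  n_perm: 500
  t_crit: 1.96
  alpha: 0.05
threshold:
  rule: proportional
  p: 0.2
cortex:
  n_channels: 64          # overdetermined toy fixture: one source per region
  n_sources: 62
  duration: 8
  source_a: 5             # planted active source, subject A
  source_b: 11            # coupled source, subject B
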