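# Full default configuration for runPipeline().  Any value omitted here (or
# in a user config) falls back to defaultPipelineConfig().
cohort:
  n_subjects: 10          # 5 female, 5 male
  volume_cv: 0.25         # lognormal nucleus volume CV (two-fold range at n=10)
  position_jitter_sd: 1.0 # mm, per-subject translation
  rotation_jitter_sd: 2.0 # degrees, per-subject rotation
  scale_jitter_sd: 0.02   # per-subject global log-scale sd
  voxel_size: 0.5         # mm, subject grids
  seed: 20
sectioning:
  thickness: 0.020        # mm (20 um sections)
  interval: 15            # every 15th section -> 300 um spacing
  offset_policy: random   # sampling lattice phase drawn per subject
  seed: 21
volumetry:
  normalization: proportion   # structure volume / total brain volume
stats:
  n_iter: 10000           # Monte-Carlo relabelings (10^6 for full runs)
  seed: 22
  sided: two
probmap:
  grid_dim: [80, 50, 40]
  grid_origin: [-40.0, -45.0, -25.0]
  voxel_size: 1           # mm, published probability-map resolution
  threshold: 0
mesh:
  smooth_iter: 10
  smooth_step: 0.1
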