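# Example end-to-end configuration: two seeding densities, directed motion,
# ground-truth (non-imaging) analysis route. Load with read_pipeline_config().
simulation:
  mode: directed
  v0: 2.0          # um/h
  duration: 12     # days
  frame_interval: 0.25
densities: [30.0, 120.0]
replicates: 2
seed: 14
analysis:
  kernel_width: 8      # um, EDF variance window
  opening_radius: 15   # um, bulk/protrusion separation
  min_radius: 50       # um, small-object cutoff
  use_imaging: false
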