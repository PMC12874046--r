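# Demonstration pipeline configuration: a reduced cohort that runs the
# full synthetic pipeline in a few minutes on one CPU. Omitted keys take
# the package defaults (printed into each stage's config_resolved.yaml).
seed: 1
sim:
  n_scale: 0.4
  contacts_per_cell: 5000
  cg_spacing: 20000
  ch_spacing: 40000
  ccc_spacing: 100000
structure:
  boundary_B: 20
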