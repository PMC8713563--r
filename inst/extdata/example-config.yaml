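# Example pipeline configuration. Unknown keys are rejected; anything
# omitted keeps the package default.
seed: 11
sim:
  n_subjects: 60
  grid_shape: [20, 20, 12]
glm:
  parameter: alpha
  n_perm: 500
network:
  p_thresh: 1.0e-6
  fdr_thresh: 1.0e-4
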