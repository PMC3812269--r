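clustering:
  cutoff: 0.6
  block: 1000
simulation:
  n_steps: 50000
  stride: 1000
seed: 42
out_dir: "fullermem-report"
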