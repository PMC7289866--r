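# Example configuration: seeded simulation of the full pipeline.
seed: 42
simulate:
  n_individuals: 17
  n_events: 92
  noise_cv: 0.05
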