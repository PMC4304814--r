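# Example end-to-end config for `erpride run`
source: simulate
sim:
  n_subjects: 4
  trials_per_condition: 20
  noise_sd: 8
ride:
  c1_window: [200, 600]
  c2_window: [400, 800]
  latency_channels: [Cz, CPz, Pz]
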