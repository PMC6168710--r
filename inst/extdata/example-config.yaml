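# Minimal simulate -> evaluate experiment: one session, two decoders.
sessions: [2]
decoders: [naive, stbf]
cues_per_target: 10
simulation:
  n_channels: 4
  snr: 1.0
  phase_jitter_sd: 0.2
  mixing_mode: localized
evaluation:
  n_folds: 5
  lengths: [0.5, 1.0, 2.0, 4.0]
seed: 11
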