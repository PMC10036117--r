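# Demo pipeline configuration: a small mixed cohort through every stage.
mode: simulate
seed: 20260929
out_dir: ymaze_demo_out
cohort:
  group_sizes:
    - {age_group: children, condition: landmark, n: 6}
    - {age_group: young,    condition: landmark, n: 6}
    - {age_group: older,    condition: landmark, n: 6}
    - {age_group: children, condition: geometry, n: 6}
    - {age_group: young,    condition: geometry, n: 6}
    - {age_group: older,    condition: geometry, n: 6}
  streams: full
gaze:
  phases: [test]
predict:
  scheme: both
  reps: 200
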