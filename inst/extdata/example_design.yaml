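# four-cohort study design: retest control plus three training cohorts
RCC:
  size: 90
  schedule: []
TC1:
  size: 80
  schedule: [Presence, Affect, Perspective]
TC2:
  size: 81
  schedule: [Presence, Perspective, Affect]
TC3:
  size: 81
  schedule: [Affect]
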