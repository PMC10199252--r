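# planted improvement effects (standardized mean change vs retest)
Presence:
  pcs_helplessness: 0.24
  tics_work_demands: 0.24
  tics_social_overload: 0.24
Affect:
  fbl_sensory: 0.30
  adhd_attention: 0.30
  adhd_impulsivity: 0.30
  fbl_emotional_reactivity: 0.30
  stai_trait_anxiety: 0.30
  fbl_cardiovascular: 0.30
  mach_total: 0.30
  ius_negative_affect_uncertainty: 0.30
Perspective:
  pss_total: 0.32
  tics_lack_social_recognition: 0.32
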