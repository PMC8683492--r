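# Default run configuration: the published protocol and the default
# synthetic observer. Any key may be overridden; unknown keys are rejected.
seed: 1
cohort:
  n_subjects: 28
design:
  exogenous:
    trials_per_cell: 10
  endogenous:
    trials_per_cell: 10
observer:
  lapse: 0.01
analysis:
  m_alternatives: 12
  benefit_ctoa:
    exogenous: 50
    endogenous: 600
  correlation: pearson
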