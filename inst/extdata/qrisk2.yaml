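name: qrisk2
description: >
  QRISK2 10-year cardiovascular risk score used as a directive rule at the
  20% predicted-risk cut-point; values from the external validation cohort
  for males aged 35-74.
prevalence: 0.09
c_statistic: 0.77
summaries:
  - label: ">=20%"
    sensitivity: 0.40
    specificity: 0.88
    prevalence: 0.09
    note: >
      Sensitivity and specificity estimated from the natural frequencies
      reported in the external validation cohort.
counts:
  cutpoint_20:
    tp: 36
    fp: 110
    fn: 54
    tn: 800
    note: >
      Per 1000 males: 90 events of which 36 are identified at risk; 110 of
      the 910 non-events are flagged at risk (the printed specificity 88%
      is itself rounded from 800/910).
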