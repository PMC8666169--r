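name: csrs
description: >
  Canadian Syncope Risk Score: risk of a serious adverse event among
  patients presenting to the emergency department with syncope. Summary
  values as printed in the score's development report (internal
  validation); cell counts per 1000 derived from the published prose.
prevalence: 0.03647
c_statistic: 0.88
summaries:
  - label: "low risk (tabulated specificity)"
    sensitivity: 0.93
    specificity: 0.53
    prevalence: 0.03647
    note: >
      Specificity printed as 53% in the tabulated case-study summary.
  - label: "low risk (diagram specificity)"
    sensitivity: 0.93
    specificity: 0.56
    prevalence: 0.03647
    note: >
      Specificity printed as 56% in the population-diagram caption; the
      prose-consistent cells (460 at risk of 1000) imply about 55.8%. Both
      printed variants are retained; neither is canonical.
counts:
  low_risk:
    tp: 34
    fp: 426
    fn: 2
    tn: 538
    note: >
      Derived from the published prose: 460 of 1000 classified at risk, 36
      events in total, and only 2 events among the 540 classified low risk
      (hence tp = 34).
  cutpoint_3:
    tp: 24
    fp: 95
    fn: 12
    tn: 869
    note: >
      Derived from the published prose: raising the cut-point to 3 reduces
      the at-risk count from 460 to 119 and increases missed events from 2
      to 12; with 36 events total this forces tp = 24, fp = 95, tn = 869.
synthetic_sweep:
  - label: "very low (synthetic)"
    sensitivity: 0.99
    specificity: 0.26
    prevalence: 0.03647
  - label: "low risk (diagram specificity)"
    sensitivity: 0.93
    specificity: 0.56
    prevalence: 0.03647
  - label: "high (synthetic)"
    sensitivity: 0.67
    specificity: 0.90
    prevalence: 0.03647
  - label: "very high (synthetic)"
    sensitivity: 0.40
    specificity: 0.97
    prevalence: 0.03647
synthetic_sweep_note: >
  Only the "low risk" cut-point's sensitivity and specificity are printed
  in the available source text; the other three cut-point rows are
  synthetic values chosen to illustrate a four-row trade-off sweep and are
  labelled accordingly.
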