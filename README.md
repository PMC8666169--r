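# natfreq

Natural frequencies and population diagrams for communicating the
trade-offs of clinical prediction rules.

## The problem

Clinical prediction models are routinely turned into directive *prediction
rules* by dichotomising predicted risk at a cut-point (low vs high risk).
The usual performance summaries — the C-statistic, sensitivity/specificity,
predictive values — either ignore the cut-point entirely or state the
trade-offs as conditional probabilities that are widely misread, even by
health professionals. The trade-offs become much easier to grasp as
**natural frequencies**: whole-person counts of true/false positives and
negatives on a reference population (per 1000 people), optionally drawn as
a **population diagram** — one icon per person, coded two ways, by event
status (shaded/unshaded) and by rule classification (red = at risk,
green = not at risk).

For a rule with sensitivity *se*, specificity *sp* and event prevalence *p*
on a reference population of *N* people, the package derives

- events = ⟦*p·N*⟧, TP = ⟦*se·p·N*⟧, FN = events − TP,
- non-events = *N* − events, TN = ⟦*sp·(1−p)·N*⟧, FP = non-events − TN,

where ⟦·⟧ rounds half away from zero and TP/TN are rounded from the
*unrounded* real products. From these cells it computes predictive values,
the overtreatment ratio FP/TP ("for every person identified as needing
treatment, another *k* treated unnecessarily") and the missed fraction
FN/events, tabulates them across cut-points or prevalences, and renders
deterministic SVG icon arrays. The conventional comparators are included:
the Mann–Whitney C-statistic for individual-level predictions and
decision-curve net benefit, NB = TP/N − (FP/N)·t/(1−t) at threshold
probability t, against treat-all and treat-none.

Intended users: authors reporting a prediction rule's performance,
guideline and impact-study developers choosing candidate cut-points, and
anyone translating model performance for health professionals.

## Worked example

The QRISK2 cardiovascular score, used as a directive rule at the 20%
predicted-risk cut-point (external validation, males 35–74: sensitivity
40%, specificity 88%, 10-year prevalence 0.09):

```r
library(natfreq)
t <- nf_from_summary(perf_summary(0.40, 0.88, 0.09, ">=20%"))
t
#> Natural frequencies per 1000 people
#>             event no event
#> at risk        36      109
#> not at risk    54      801
nf_metrics(t)
#> Per-cut-point metrics
#>   events 90 / 1000 (at risk 145, not at risk 855)
#>   sensitivity  0.4  specificity 0.88  PPV 0.248  NPV 0.937
#>   overtreatment ratio 3.03 FP per TP; missed fraction  0.6 of events
```

Read as counts: of 1000 men, 90 will have a cardiovascular event; the rule
flags 145 as at risk but catches only 36 of the 90 — for every man
correctly identified, another 3 are treated unnecessarily, and two thirds
of those in need of treatment are missed. None of this is visible in the
score's C-statistic of 0.77 alone.

The packaged syncope-score case study compares two cut-points as a
trade-off table (cells from the published prose):

```r
fx <- case_study_fixture("csrs")
sw <- sweep_from_tables(fx$counts[c("low_risk", "cutpoint_3")])
cat(sweep_to_table(sw, "markdown"))
```

| label | tp | fp | fn | tn | at_risk | not_at_risk | sensitivity | specificity | ppv | npv | overtreat_ratio | missed_fraction |
| --- | --- | --- | --- | --- | --- | --- | --- | --- | --- | --- | --- | --- |
| low_risk | 34 | 426 | 2 | 538 | 460 | 540 | 0.94 | 0.56 | 0.07 | 1.00 | 12.53 | 0.06 |
| cutpoint_3 | 24 | 95 | 12 | 869 | 119 | 881 | 0.67 | 0.90 | 0.20 | 0.99 | 3.96 | 0.33 |

Raising the cut-point shrinks the at-risk class from 460 to 119 people at
the cost of missing 12 events instead of 2. A population diagram of either
row is one call away:

```r
svg <- render_svg(nf_layout(fx$counts$low_risk), file = "csrs.svg")
# 1000 icons: 460 on red cells (at risk), 36 shaded (events)
```

`run_report()` ties it together — sweep table, one diagram per cut-point,
and a generated narrative in whole-person counts — from a small YAML
config; `inst/cli/natfreq.R` exposes the same pipeline as shell
subcommands (`report`, `sweep`, `diagram`, `simulate`, `fixtures`).

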