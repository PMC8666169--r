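---
title: "Natural frequencies, population diagrams, and the trade-offs of prediction rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural frequencies, population diagrams, and the trade-offs of prediction rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natfreq)
```

## The model of communication this package implements

A prediction model becomes a prediction *rule* when predicted risk is
dichotomised at a cut-point and care is stratified accordingly. At that
point its performance is fully described, for one population, by three
numbers: sensitivity and specificity at the cut-point, and the prevalence
of the event. The package's central move is to re-express those three
conditional quantities as four *joint* whole-person counts on a reference
population — the natural frequencies TP, FP, FN, TN — because joint counts
are what people, including health professionals, demonstrably read
correctly, and because they combine the predictive values with the baseline
risk that conditional metrics leave out.

Everything else follows from that 2×2 object: predictive values and
trade-off ratios (`nf_metrics()`), tables across cut-points or prevalences
(`sweep_cutpoints()`, `sweep_prevalence()`), icon-array population diagrams
(`nf_layout()`, `render_svg()`), and the decision-analytic comparison via
net benefit (`net_benefit()`, `decision_curve()`).

## Deriving the cells: the rounding convention

With sensitivity $se$, specificity $sp$, prevalence $p$ and population $N$:

$$\mathrm{events} = \left[ pN \right],\quad
  \mathrm{TP} = \left[ se \cdot pN \right],\quad
  \mathrm{FN} = \mathrm{events} - \mathrm{TP},$$
$$\mathrm{non\text{-}events} = N - \mathrm{events},\quad
  \mathrm{TN} = \left[ sp \cdot (1-p)N \right],\quad
  \mathrm{FP} = \mathrm{non\text{-}events} - \mathrm{TN},$$

where $[\cdot]$ rounds half away from zero. Two details matter and were
deliberate choices:

* **TP and TN are rounded from the unrounded real products**, not computed
  against the already-rounded margins. At sensitivity 0.93 and prevalence
  0.03647 per 1000, the events margin is $[36.47] = 36$ and
  $\mathrm{TP} = [33.917] = 34$, so 2 events are missed. Rounding 0.93
  against the pre-rounded margin ($[0.93 \times 36] = [33.48] = 33$) gives a
  different, less faithful cell.
* **Half away from zero**, not R's default half-to-even: printed
  percentages are themselves half-away-rounded, and banker's rounding would
  turn 36.5 expected events into 36 rather than 37.

Rounding is monotone, so a derived cell can only go negative in one edge
case: both margins landing exactly on .5 (e.g. $pN = 36.5$ with $sp = 1$,
where $[963.5] = 964$ exceeds the 963 non-events). The cell is clamped to
zero, the neighbouring cell adjusted to conserve the population, and the
table flagged `"clamped"` with a warning. Undefined metrics (zero
denominators, e.g. PPV when nobody is classified at risk) are never errors:
they are `NA`, named in the `undefined` field, and rendered as an em dash
in tables, so a sweep containing an extreme cut-point still prints.

Round-tripping is exact up to integer resolution: the sensitivity recovered
from a derived table is within $1/\mathrm{events}$ of the input, and
analogously for specificity.

## Individual-level predictions

When per-subject predicted risks and outcomes are available
(`pred_data()`, `read_predictions()`), classification uses an **inclusive
threshold**: risk ≥ cut-point means "at risk". This matches the directive
reading of "risk of 20% or more"; a source using the exclusive convention
can negate its scores. Ties therefore go to the at-risk class. The
C-statistic (`c_statistic()`) is the Mann–Whitney concordance — the
probability a random event subject outranks a random non-event subject,
ties counting one half — computed from mid-ranks in $O(n \log n)$; tests
verify exact agreement with an $O(n^2)$ pairwise loop and with an
independent ROC implementation, and its invariance under strictly
increasing transforms of the risks.

## Sweeps

A cut-point sweep presumes one population: `sweep_cutpoints()` rejects
summaries with differing prevalences rather than silently mixing them,
since a table whose rows describe different populations invites meaningless
column comparisons. Prediction-based sweeps sort cut-points ascending, and
the at-risk count is then non-increasing by construction. Prevalence sweeps
hold sensitivity and specificity fixed — the standard transportability
assumption — and show how the same rule plays out under different baseline
risks. Rendered tables default to 2 decimal places for proportions
(percent-style reporting); counts are always integers.

## Population diagrams

The diagram gives each of the $N$ people one icon, coded two ways: the cell
behind the icon is coloured by rule classification (red = at risk, green =
not at risk by default; a colour-blind-safe Okabe–Ito pairing is a preset,
and all colours are overridable), and the icon is shaded if the person has
the event. Choices the source material leaves open, decided here and
configurable:

* **Grid shape**: 25 columns × 40 rows for the default population of 1000 —
  a compact, near-portrait aspect ratio. Any grid with capacity ≥ N is
  accepted; a too-small grid is a loud error, never a silent truncation.
* **Icon ordering**: group-contiguous blocks in the order TP, FP, FN, TN,
  filled row-major from the top-left, so the at-risk region reads as one
  coloured block and the FN icons sit visibly at its boundary. A scattered
  arrangement (`arrange = "scatter"`) is available and requires an explicit
  seed, so it is exactly reproducible.
* **Determinism**: `render_svg()` is a pure function of layout and style —
  fixed float formatting (2 decimals), a positional id scheme, no
  timestamps — so identical inputs give byte-identical SVG and diffs
  between renders are stable. `render_diagram_pair()` renders two tables
  with shared grid and styling for cut-point comparisons, refusing
  mismatched populations.

## Net benefit

The decision-curve comparison uses the standard net-benefit definition
$\mathrm{NB}(t) = \mathrm{TP}/N - (\mathrm{FP}/N)\,t/(1-t)$, which is
external to the natural-frequency method itself but is its conventional
decision-analytic companion. Treat-none is identically 0; treat-all equals
$p - (1-p)\,t/(1-t)$, zero exactly at $t = p$; no rule can exceed $p$.
When only a summary-level table exists, the rule's cells are held fixed
across thresholds — a documented limitation, since re-classification per
threshold requires individual-level data. Thresholds are required to lie
strictly inside (0, 1); the odds weight degenerates at the endpoints.

## The synthetic-data generator

`simulate_scores()` draws outcomes Bernoulli($p$) and scores from the
equal-variance binormal model: non-events $\mathcal{N}(0,1)$, events
$\mathcal{N}(\mu, 1)$ with $\mu = \sqrt{2}\,\Phi^{-1}(C)$, the closed-form
link between separation and the C-statistic. Scores map to $(0,1)$ risks
through the logistic function, which is strictly increasing and so leaves
every rank statistic — including the C-statistic — untouched. The generator
emulates the discrimination of realistic rules (the packaged case studies
report C-statistics of 0.77 and 0.88); it does **not** emulate calibration
(simulated risks are not the true event probabilities), clustering,
missingness, or case-mix heterogeneity. Passing tests therefore certify the
arithmetic and rank machinery on well-behaved inputs, not rule performance
on real cohorts.

Default study conditions follow the packaged cardiovascular case study:
prevalence 0.09, target C 0.77, and $n = 40{,}000$ where convergence is
asserted — at that size the Monte-Carlo standard error of the empirical C
is well under the ±0.01 band checked by the tests, and the run takes well
under a second. Property tests use $n \le 200$ against brute-force oracles,
where exhaustive per-subject and per-pair checks are cheap.

## Case-study fixtures

`case_study_fixture()` ships the two worked examples as data
(`inst/extdata/*.yaml`), each with a provenance note per entry:

* **csrs** — syncope score, prevalence 0.03647, sensitivity 93% at the
  "low risk" cut-point. The published specificity appears as 53% in the
  tabulated summary but 56% in the diagram caption, and the prose-derived
  cells (460 of 1000 at risk) imply ≈55.8%; all variants are retained,
  none promoted to canonical. Cells for the cut-point-3 comparison
  (119 at risk, 12 missed) are forced by arithmetic from the published
  prose and 36 total events. A four-row sweep demonstration is included
  whose three non-"low risk" rows are synthetic and labelled as such —
  only the low-risk cut-point's operating characteristics are printed in
  the available source text.
* **qrisk2** — cardiovascular score at the 20% cut-point, prevalence 0.09,
  sensitivity 40%, specificity 88%, C 0.77, cells (36, 110, 54, 800). Note
  the printed specificity is itself rounded from 800/910, so re-deriving
  the cells from 0.88 gives 801/109 — one person off the reported counts.
  Count-based entry (`nf_table()`, `sweep_from_tables()`) exists precisely
  so reported cells can be used verbatim; `run_report()` prefers a
  fixture's counts for this reason (`source: summaries` opts into
  re-derivation).

## Reporting surface

`validate_config()` parses YAML or JSON, collects *all* problems with field
paths rather than failing fast, and returns them as a value. `run_report()`
emits the sweep table (CSV/Markdown/HTML), one diagram per row, and a short
narrative per row whose every number is interpolated from the same table
objects the sweep holds — never recomputed ad hoc — so narrative and table
cannot disagree. Narrative wording lives in `inst/templates/` as data, not
code. With a fixed configuration the whole bundle is byte-identical across
runs.

## Known limitations

Confidence intervals for metrics, calibration assessment, optimal-cut-point
selection (cut-point choice is framed as a contextual trade-off, not an
optimisation), interventions-avoided rescaling of net benefit, and scaled
rectangular diagrams are all out of scope.
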