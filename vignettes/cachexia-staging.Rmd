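---
title: "Staging cancer cachexia from routine clinical data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging cancer cachexia from routine clinical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachexstage)
```

## The classification model

Cancer-associated cachexia progresses along a continuum, and treating it
as a binary (cachectic / not) discards the pre-cachectic window where
intervention is most useful. The package implements a four-stage
classification — non-cachexia (NCa), pre-cachexia (PCa), cachexia (Ca),
refractory cachexia (RCa) — driven entirely by data available in routine
care: a small laboratory panel and two boxes of the abridged PG-SGA.

Six criterion flags are derived per patient:

* **A** — abnormal biochemistry, a missing-aware OR over four components:
  CRP > 10 mg/L, albumin < 3.2 g/dL, WBC > 11,000 cells/µL, and
  sex-specific anemia (hemoglobin < 12 g/dL in men, < 11 g/dL in women).
* **B** — decreased food intake, aPG-SGA box 2 > 1.
* **C** / **D** — weight loss over the prior 6 months,
  `100 * (prior - current) / prior`: minimal (0 < WL ≤ 5%) or significant
  (WL > 5%). They are mutually exclusive by construction, and a
  weight-stable or weight-gaining patient meets neither — "minimal loss"
  requires that loss occurred, otherwise weight-stable patients would
  drift into PCa through C.
* **E** / **F** — activity, aPG-SGA box 4: preserved (≤ 2) or impaired
  (> 2; equivalent to an ECOG performance score above 3). Self-reported
  grip-strength items are stored in the record but never enter staging
  (a dynamometer criterion is not generally collectable in multi-center
  practice).
* **Alb\*** — severe hypoalbuminemia (< 2.5 g/dL), which opens the
  refractory routes.

Stage blocks are evaluated in severity order, first match wins, and the
matching combination is recorded (`rule_fired`) for audit:

* RCa: `A+D+F`, `B+D+F`, `A+B+D+F`, `Alb*+D`, `Alb*+E`, `Alb*+D+F`
* Ca: `A+D+E`, `B+D+E`, `A+B+D+E`, plus the rule that **any** patient
  with D who reaches no RCa combination is cachectic
* PCa: `A+B`, `A+C`, `B+C`, `A+B+C`
* NCa: no combination matched

The `D`-rule deserves a note: taken literally, "significant weight loss
with no other symptoms" only covers D alone, but the structure of the
classification (no D among NCa/PCa, D universal among Ca/RCa) forces the
generalization "D that does not reach refractory is cachectic", which is
what the package implements. The `Alb*+E` route is unusual in pairing
severe hypoalbuminemia with *preserved* activity; it is implemented as
printed. Precedence (RCa over Ca over PCa) resolves flag sets satisfying
several blocks at once, assigning the most severe matching stage, which
is what makes the four stages a partition.

The implementation is a rule table; the test suite contains an
independently written brute-force enumerator of the combination lists and
checks agreement on all `2^7 = 128` flag patterns, including incoherent
ones (C and D together, E and F together) so that precedence is pinned
down everywhere, not only on reachable patterns.

### Missing data semantics

Three rules, applied consistently:

1. A missing value is `NA` end to end (empty cell on disk); it can never
   satisfy a threshold.
2. An unmeasured criterion counts as *not met* during rule matching. This
   mirrors clinical reality: patients with incomplete labs still get
   staged, and the alternative (propagating `NA` into the stage) would
   discard most of a real cohort.
3. The one exception is weight history: without a 6-month-prior weight
   neither C nor D is decidable, and both the four-stage label and the
   dichotomous status are `Unstageable`. Unstageable patients are excluded
   from every prevalence denominator.

The dichotomous weight-loss status (cachectic: WL > 5%, or BMI < 20 kg/m²
with WL > 2%) is computed alongside the four stages because sparse
complete-data categories make the full classification fragile in small
strata.

### Laboratory derivations

The Glasgow Prognostic Score uses CRP > 10 mg/L (the canonical-unit
equivalent of 1.0 mg/dL) and albumin < 3.5 g/dL: both abnormal scores 2,
exactly one scores 1, neither scores 0. Since no single component forces
a unique score, GPS is `NA` whenever either component is unmeasured. The
neutrophil-to-lymphocyte ratio is flagged at ≥ 5 — the only non-strict
comparator in the package; every other threshold is strict as printed.
CRP provenance matters (standard-of-care EMR values are scarce; a
research assay on banked serum fills the gap), so the record carries both
and `crp_value()` prefers the standard-of-care value while recording the
source used.

Canonical units are fixed once (CRP mg/L; albumin and hemoglobin g/dL;
counts per µL; platelets 10³/µL; bilirubin mg/dL; CA19-9 U/mL), and
`read_cohort()` converts declared alternate units exactly once at ingest.
Threshold tables sometimes mix unit notations (mg/dL vs g/dL for albumin,
g/L vs g/dL for hemoglobin); the package resolves these on physiologic
plausibility — an albumin cut of 3.2 is meaningful in g/dL, not mg/dL —
and keeps all comparisons in canonical units.

## Instrument scoring

**ESAS-r.** Physical subscore: mean of pain, tiredness, drowsiness,
nausea, appetite, shortness of breath. Psychological: mean of anxiety and
depression. Total: mean of all scored items — wellbeing included by
default, since it is a scored symptom item, with the item list exposed as
an argument because conventions differ. Partial panels are averaged over
available items with no imputation; rows with under half the items
answered carry a `low_coverage` flag so analysts can sensitivity-check.
Items and subscores dichotomize at ≥ 4 into moderate-to-severe.

**EORTC QLQ-C30 / QLQ-PAN26.** Standard linear transforms to 0–100 from
the raw scale score (mean of member items): functional scales and global
health oriented so 100 is best, symptom scales so 100 is worst; a scale
with at least half its member items answered is scored from the answered
items, otherwise `NA`. Scale membership ships as a versioned JSON
resource (`inst/extdata/instrument_scales.json`) rather than code, so a
scoring revision is a data change. For PAN26 every scale is reported on
the symptom orientation with a per-scale direction attribute; only
healthcare satisfaction is higher-is-better. (Scoring manuals also treat
the sexuality scale as functional; the package follows the simpler
satisfaction-only convention of the study design it emulates, and the
direction metadata makes either reading explicit.)

**Canadian Problem Checklist.** Ticked problems are item identifiers
grouped in seven domains; the summary counts per domain and reports a
deterministic top domain with ties broken by a fixed order (emotional,
physical, informational, practical, spiritual, social, family) so that
repeated runs never disagree on rank-1.

## The synthetic cohort generator

The generator exists so that every pipeline step — ingest, scoring,
staging, tables, survival — can be tested end to end with known truth.
Its defaults are the study conditions, fixed once:

* stage mix 40 : 76 : 167 : 26 (the enrollment counts over 309 stageable
  cases), drawn either by quota (largest-remainder, exact counts, for
  table arithmetic) or multinomially (for simulation studies);
* per-stage criterion and marker rates from the published criterion
  prevalence table, using full-stage denominators (NA rows included, as
  that table does); where a flag-level rate is not printed (A, C), a
  plausible marginal was chosen once: A = 0 / 0.55 / 0.45 / 0.75 and
  C = 0.30 / 0.60 / 0 / 0 across NCa / PCa / Ca / RCa;
* demographics: 50.6% female; NHW : AA : HL = 236 : 35 : 47;
* survival: exponential by default (Weibull shape exposed; any shape
  keeps the hazard ratios proportional) with reference median 14.6
  months and stage hazard ratios 1 / 1.50 / 1.87 / 3.24; censoring
  fraction 0.43, the cohort's alive-or-unknown fraction.

**Stage-consistent sampling.** Criterion patterns are not drawn
independently: the generator enumerates the 64-point flag space
(A, B, C, D, F, Alb\*; E is the complement of F; C·D and Alb\*·¬A are
excluded — the latter because albumin < 2.5 implies albumin < 3.2, which
is a component of A), weights each pattern by the per-stage proposal
marginals, classifies each pattern with the *same* `classify_stage()`
users call, and samples from the conditional distribution given the
generating stage. Consequently recovery is exact by construction —
`stage_cohort()` on a noise-free generated cohort returns the generating
stage for 100% of patients — and the configured rates are proposal
marginals, not realized prevalences (the conditioning reshapes them, just
as the real table's prevalences are shaped by the rule set). A rate that
no pattern in a stage's conditional support can express (e.g. any D for
NCa) is a config error rather than a silent renormalization.

Raw values are then placed strictly inside/outside each threshold
(uniform bands of roughly ±50% around the cut, on the correct side), so
the threshold and unit code is genuinely exercised rather than bypassed.

**Censoring.** Censoring times are `C ~ Uniform(0, τ)` with τ solved
numerically so the expected censored fraction hits the target. Because
`C` is independent of the event time, the Kaplan–Meier estimator remains
consistent — the simpler shortcut of censoring at a uniform fraction *of
the event time* is not independent censoring and biases the median
downward, which matters when the tests assert median recovery.

**What the generator does not emulate.** Correlations among labs beyond
stage-conditioning; realistic item-level questionnaire response patterns
(QLQ/PAN items are uniform; box and domain scores are back-filled to
match flags); informative censoring; measurement error in self-reported
weight. Passing tests therefore demonstrate that the pipeline is correct
*given* the staging model, not that the staging model is correct for
real patients.

## Statistical methods

Chi-square (Pearson, no continuity correction, expected-count warning
below 5), Kruskal–Wallis, and the proportional-hazards solver are
delegated to the standard routines — their formulas are settled — while
the quantities that carry the headline contrasts are implemented in the
package and cross-checked against independent references in the tests:

* **Kaplan–Meier**: product-limit over distinct event times, Greenwood
  variance, log-log confidence bands, median as the first time
  `S(t) ≤ 0.5`, median CI from where the bands cross 0.5. Verified
  against hand-computed fixtures and `survival::survfit`.
* **Log-rank**: k-group observed-vs-expected with the hypergeometric
  covariance, quadratic form with one group dropped, `k − 1` df.
  Verified against `survival::survdiff`.
* **Cochran–Armitage trend** across the ordered stages (scores 0–3 by
  default): `Z = Σ wᵢ(yᵢ − nᵢ·p̄) / sqrt(p̄(1−p̄)(Σ nᵢwᵢ² − (Σ nᵢwᵢ)²/N))`,
  two-sided normal p. Verified against a 10⁴-draw permutation oracle
  (mid-p); on tables of 4 × 30–60 the asymptotic p tracks the skewed
  discrete permutation distribution to within a few hundredths, which is
  the agreement the test asserts.

Cox fits use Efron tie handling (lower bias than Breslow, a default the
data cannot overrule since the tie structure is continuous in months);
ordered factors are refit with treatment contrasts so coefficients are
hazard ratios against the reference level (NCa, NHW, female, stage I/II
in typical encodings). Non-convergence, constant covariates, and
separation (unbounded coefficients) raise errors naming the covariate.
No multiplicity adjustment is applied by default — analyses report raw
p-values, and `stats::p.adjust` composes trivially where wanted.

Percentages round half-up (one decimal in stage summaries, two in
criterion tables) because base R's round-half-even disagrees with
hand-tabulated percentages at .5 boundaries. One consequence accepted
deliberately: 167/309 = 54.045% prints as 54.0 here even though the
emulated study table shows 54.1.

## Problem sizes and determinism

The test suite runs at sizes chosen to keep Monte-Carlo assertions
meaningful: oracle equivalence on all 128 patterns; stage recovery at
n = 1000; exponential-median recovery at n = 20,000 (sampling sd of the
median ≈ 0.17 months, so the asserted 0.7-month bound is > 4 sd);
Kaplan–Meier median within 0.5 months at n = 5000 with 20% censoring;
Cox recovery of a 3.24 hazard ratio within 15% at 2500 per arm; CI
coverage of the generating hazard ratios (1.50 / 1.87 / 3.24) in ≥ 90%
of 50 replicates at 1250 per arm. All stochastic tests fix seeds;
`generate_cohort()` is byte-identical for identical config.

## Known limitations

* The classification cannot separate PCa from Ca well on cross-sectional
  data — criteria distinguish NCa from everything else far better than
  adjacent middle stages, and the generator reproduces that structure
  rather than fixing it.
* Activity and intake are self-reported box scores; the package treats
  the published numeric cuts as exact and takes no position on
  instrument coding variants beyond them.
* The `Alb*+E` refractory route is implemented as printed even though
  pairing severe hypoalbuminemia with preserved activity is clinically
  surprising; auditors can find such patients via `rule_fired`.
* No ordination/correspondence analysis, no registry linkage, no imaging
  or body-composition inputs, no longitudinal mixed-effects modelling:
  the package stages at a timepoint and analyzes from there.
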