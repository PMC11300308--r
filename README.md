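# cachexstage

Rule-based staging of cancer-associated cachexia in pancreatic ductal
adenocarcinoma (PDAC), with the downstream prevalence, symptom-burden, and
survival analyses that a staging study needs — plus a seeded synthetic-cohort
generator so the whole pipeline is testable without patient data.

Cachexia is a wasting syndrome (weight loss, muscle atrophy, anorexia,
systemic inflammation) that affects most PDAC patients and worsens both
quality of life and survival. The package is aimed at clinical
epidemiologists and biostatisticians who want a reproducible, auditable
implementation of a four-stage classification built from data available in
routine care.

## The classification

Each patient is scored on criterion flags derived from labs and the
abridged Patient-Generated Subjective Global Assessment (aPG-SGA):

| Flag | Meaning |
|------|---------|
| A | abnormal biochemistry: CRP > 10 mg/L, albumin < 3.2 g/dL, WBC > 11,000/µL, or hemoglobin < 12 g/dL (men) / < 11 g/dL (women) |
| B | decreased food intake (aPG-SGA box 2 > 1) |
| C | minimal weight loss: 0 < WL ≤ 5% over 6 months |
| D | significant weight loss: WL > 5% over 6 months |
| E / F | preserved (box 4 ≤ 2) / impaired (box 4 > 2) activity |
| Alb* | severe hypoalbuminemia: albumin < 2.5 g/dL |

Stages are assigned by combination rules, evaluated in severity order:

- **RCa** (refractory): A+D+F, B+D+F, A+B+D+F, Alb\*+D, Alb\*+E, Alb\*+D+F
- **Ca** (cachexia): A+D+E, B+D+E, A+B+D+E — and any patient with D who
  reaches no RCa combination
- **PCa** (pre-cachexia): A+B, A+C, B+C, A+B+C
- **NCa** (non-cachexia): none of the above

A missing 6-month-prior weight makes a patient *Unstageable*; any other
unmeasured criterion counts as "not met". A dichotomous status (cachectic
vs non-cachectic) is also computed: WL > 5%, or BMI < 20 kg/m² with
WL > 2%.

Around the classifier the package provides: ESAS-r symptom subscores
(dichotomized at ≥ 4 as moderate-to-severe), EORTC QLQ-C30 / QLQ-PAN26
0–100 scale scoring, Canadian Problem Checklist domain tallies, the
Glasgow Prognostic Score and neutrophil-to-lymphocyte ratio,
criterion-prevalence tables, chi-square / Kruskal–Wallis / Cochran–Armitage
trend tests, a product-limit (Kaplan–Meier) estimator with Greenwood
variance, the k-group log-rank test, and a proportional-hazards fitting
contract over `survival::coxph` (Efron ties).

## Worked example

```r
library(cachexstage)

cfg <- cohort_config(seed = 2024, n = 309, sampling = "quota")
g   <- generate_cohort(cfg)          # cohort + per-patient truth
st  <- stage_cohort(g$cohort)
st
#> Cachexia staging: 309 stageable, 0 unstageable
#>  stage   n  pct
#>    NCa  40 12.9
#>    PCa  76 24.6
#>     Ca 167 54.0
#>    RCa  26  8.4
#> Dichotomous status: cachectic=195, non_cachectic=114

mean(st$labels$label == g$truth$true_stage)   # stage recovery
#> [1] 1

fit <- cox_ph_fit(cbind(g$cohort, stage = st$labels$stage),
                  covariates = "stage")
fit
#> Proportional-hazards fit: 309 subjects, 181 events
#>      term   coef    hr  lower upper     se   p_value
#>  stagePCa 0.4473 1.564 0.8816 2.775 0.2925 1.262e-01
#>   stageCa 0.9452 2.573 1.5408 4.298 0.2617 3.041e-04
#>  stageRCa 1.2822 3.604 1.8917 6.868 0.3289 9.705e-05
```

The quota-sampled cohort reproduces the configured stage mix exactly
(40/76/167/26 of 309, i.e. 12.9/24.6/54.0/8.4%), staging recovers every
generating stage (the generator draws criterion patterns from the
conditional distribution over each stage's rule set, with raw values
placed strictly on the correct side of every threshold), and the
proportional-hazards fit estimates hazard ratios against the NCa reference
that are consistent with the generating values (1.50, 1.87, 3.24) at this
cohort size.

A thin command-line wrapper over the same functions ships at
`inst/cli/cachexstage.R` (`simulate` and `stage` subcommands).

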