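---
title: "Methods: incident CKD G3 phenotyping and competing-risk estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incident CKD G3 phenotyping and competing-risk estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdpheno)
```

## The problem

Chronic kidney disease is staged on the estimated glomerular filtration
rate (eGFR); stage G3 (eGFR 30–59 mL/min/1.73 m²) is the first stage that
routine laboratory data can detect at population scale. The clinically
urgent question for a person with *new* stage G3 disease is whether their
kidney function will decline rapidly. This package implements a complete,
testable pipeline for that question on longitudinal plasma creatinine
data: eGFR computation, exclusion of acute kidney injury (AKI) artifacts,
incident case-finding, classification of progression outcomes, and
absolute risk estimation with death as a competing risk — plus a synthetic
registry generator so that every stage can be verified against known
ground truth without access to protected health data.

## Models and definitions

### eGFR

The CKD-EPI creatinine equations (2009 primary analysis, race-free 2021 as
sensitivity) are piecewise power laws in standardized serum creatinine;
coefficients are exported by `ckdepi_constants()`. Creatinine arrives in
µmol/L and is converted at 88.42 µmol/L per mg/dL. Two deliberate
conventions:

* **No race coefficient.** Nordic registries carry no race variable; the
  race-free convention is used for both equation vintages.
* **Full precision.** eGFR is never rounded before threshold comparisons.
  Whether the original analyses rounded to integers is unknowable from
  the outside; full precision is the only self-consistent choice, and the
  half-open stage intervals ([45, 60) for G3a, etc.) reproduce printed
  inclusive integer ranges ("45–59") for integer-reported values.

### AKI exclusion

KDIGO defines AKI onset (≥26.5 µmol/L rise within 48 h, or ≥1.5× baseline)
but not episode *extent*, and chronic phenotyping must not see creatinine
measured during an episode. Decisions made here:

* Baseline for the relative criterion is the minimum creatinine over the
  preceding 7 days (KDIGO's usual short window). A measurement with no
  earlier neighbour inside the window cannot fire the relative criterion —
  a structural insensitivity of the criteria themselves on sparse series,
  visible in the tests.
* An episode runs from onset to the first measurement below 1.25× the
  pre-onset baseline, capped at 90 days. The cap bounds how much of a
  person's record one spike can erase. Overlapping episodes merge, and the
  flagged interval is closed on both ends.
* The onset measurement itself is excluded; the earlier, lower comparison
  measurement is retained.
* The 48 h comparison window is closed at exactly 48 h, and any earlier
  measurement within it may serve as the comparator (the definition does
  not restrict to the immediately preceding one).

### Incident CKD stage G3

Two or more eGFR values in [30, 60) separated by ≥90 days; the index date
is the second value of the earliest qualifying pair and its eGFR is the
*inclusion eGFR*. A person whose earliest pair completes before the
enrollment window opens is prevalent, not incident, and is excluded — as
is anyone with kidney replacement therapy (KRT) before the index date.
The substage is G3b if two values in [30, 45) ≥90 days apart exist at or
before index, else G3a. Only outpatient/primary-care measurements enter
(the `setting` column filters inpatient samples upstream), and eGFR
exactly 60 never counts toward the band, in lookback or follow-up.

### Rapid progression

A follow-up measurement m₁ qualifies when (a) its eGFR is ≥5 below the
inclusion eGFR, (b) the ordinary-least-squares slope over m₁ and all
measurements in the preceding 365 days is ≤ −5 mL/min/1.73 m²/year, and
(c) that window holds ≥3 measurements spanning ≥90 days from its first
measurement to m₁. In the primary (confirmed) definition m₁ must be
followed 30–180 days later (both ends inclusive) by a measurement that is
≤ eGFR(m₁) or itself satisfies (a)–(c); the event date is the *first*
confirmatory measurement's date. Choices where the definition is silent:

* Candidates are scanned chronologically and a candidate that fails
  confirmation does not end the search; the earliest confirmed date over
  all candidates is returned. This maximizes sensitivity and matches the
  "first confirmatory" wording.
* The slope window is (m₁ − 365 d, m₁]; whether the inclusion measurement
  participates depends only on whether it falls inside.
* The ≥3-measurement count includes m₁ itself ("m₁ and all measurements
  taken within the preceding year").
* All value comparisons are at full floating precision; all day
  comparisons are on raw day differences.

The unconfirmed variant ("potential rapid progression") dates the event
at m₁. Secondary outcomes: *drop in GFR category* (first post-index
measurement ≤75% of the inclusion eGFR whose stage is strictly worse than
the inclusion stage — both conditions at the same measurement) and
*kidney failure* (second of the first pair of eGFR <15 ≥90 days apart,
or KRT, whichever first).

### Competing-risk estimation

Each person is followed from index to death, emigration or the
administrative end. Outcomes are coded event (1), competing death (2) or
censored (0); ties resolve events-first. The Aalen–Johansen estimator
gives cause-specific cumulative incidence
`CIF_k(t) = Σ_{s≤t} S(s−)·d_k(s)/n(s)` with the all-cause Kaplan–Meier
`S`. With no competing cause it reduces exactly to 1 − KM (tested as an
identity), and `Σ_k CIF_k(t) + S(t) = 1` at every event time
(conservation, also tested). Variance is Aalen's counting-process
estimator (computed in O(J) by cumulative-sum expansion); pointwise
intervals use the log(−log) transform, which keeps bounds inside [0, 1].
The original analyses name neither a variance estimator nor a CI
transform; these are this package's own documented choices.

One subtlety surfaced by testing: confirmed rapid-progression events are
*person-wise* a subset of potential events with equal-or-later dates, so
the event counting processes are ordered at every time point — but the
estimated CIF curves can invert by O(1/n) at small risk sets, because
moving an event later perturbs the survival weights. The acceptance test
asserts the exact subset property and the pooled 3-year ordering rather
than a pointwise inequality that no consistent estimator satisfies
exactly in finite samples.

The heat map evaluates the confirmed-rapid-progression CIF at 1 and 3
years in each sex × albuminuria × diabetes × hypertension/CVD cell.
Persons with missing uACR (two-thirds of a realistic cohort) form their
own displayed stratum — dropping them silently would misrepresent the
population. A cell with persons but no events by the horizon reports risk
0 with the exact one-sided binomial upper bound `1 − (α/2)^(1/n)` instead
of a degenerate zero-width interval.

## The synthetic registry

`simulate_cohort()` emulates the statistical structure of nationwide
laboratory/registry data. The stated world, fixed once:

| Parameter | Default | Why |
|---|---|---|
| female fraction | 0.55 | cohort marginal of the emulated registry |
| diabetes / hypertension / CVD | 0.18 / 0.62 / 0.21 | cohort marginals |
| albuminuria A1/A2/A3/missing | 0.224/0.085/0.022/0.669 | cohort counts, renormalized |
| age at epoch | N(71, 9.5) on [18, 99] years | centers age at inclusion near the observed median of 75 |
| true baseline eGFR | N(68, 8) mL/min/1.73 m² | reproduces the observed inclusion-eGFR median (~56) and the overwhelmingly-G3a composition; values just above 60 are what makes disease *incident* rather than prevalent |
| slopes: non-progressor / progressor | N(−1, 1) / N(−8, 3) per year | straddles the −5/year threshold |
| progressor log-odds | intercept logit(0.10); male +0.3, A2 +0.8, A3 +1.8, diabetes +0.5, HTN/CVD +0.5 | positive marker effects of plausible magnitude; drives the heat-map gradient |
| visit process | gamma renewal, mean gap 120 d (×0.7 if diabetic/hypertensive), shape 2 | ≈2 eGFR tests/year as observed |
| assay noise | lognormal, CV 6% | typical creatinine assay variability |
| AKI | 0.1 episodes/person-year, ×U(1.5, 3) for U(3, 14) days | transient excursions |
| death | Gompertz, 8·10⁻⁵·e^(0.09·age)/year | ≈18% 3-year mortality at age 75 |
| admissions / emigration | Poisson 0.25/yr; exponential 0.005/yr | ≈50% 3-year hospitalization; rare emigration |
| KRT | at true eGFR = 10 | exercises the kidney-failure path (no external value exists for this) |
| time frame | lookback 0–1095 d, enrollment 1095–2555 d, end 2920 d | 3-year lookback, 4-year enrollment, follow-up to study end |

One global seed governs all streams through fixed offsets (covariates +1,
trajectories +2, visits +3, noise +4, AKI +5, events +6), so runs are
byte-reproducible and streams are independently swappable. Creatinine is
obtained by closed-form inversion of the 2009 equation along the true
eGFR line (floored at 5), then multiplied by AKI excursions and noise.

What a green test does **not** establish: trajectories are linear (no
hooks or treatment effects), observation is non-informative given the
comorbidity flags (real testing intensifies when clinicians worry),
covariates are drawn independently rather than jointly, admissions are
homogeneous Poisson, and the uACR values within a stage are uniform. The
generator validates the *pipeline's logic*, not the realism of any
particular published risk figure.

## Numerical and degenerate-input choices

* Day arithmetic is plain numeric; all "≥ N days" rules compare raw
  differences, with closed/half-open conventions as stated above.
* Slope fitting uses the closed-form OLS expressions; identical times
  raise a degenerate-fit error rather than returning ±Inf.
* `aalen_johansen` accepts ties of any kind; events at a time precede
  censorings there, and different causes at one time share the hazard
  denominator. CIF = 0 or 1 gives a point-mass interval.
* `risk_at` is right-continuous; horizons beyond the last observed
  follow-up return the last value flagged `truncated`, with a warning.
* Scale-downs in the acceptance tests (declared, not tuned): end-to-end
  recovery uses 400 persons per seed across 20 seeds — the criterion's
  disagreement bound is evaluated on the pooled ~800 comparable persons —
  and the detector-oracle criterion runs 2 000 fuzzed series per detector
  (10 000 total).

## Known limitations

* The AKI criteria are structurally insensitive on sparse series (no
  baseline within 7 days means the relative criterion cannot fire), so
  simulated AKI injected far from any recent measurement is legitimately
  invisible to the filter.
* The prevalent-disease rule assumes measurement coverage through the
  lookback period; persons genuinely unobserved before enrollment cannot
  be distinguished from incident ones.
* No regression modelling of hazards is provided (none is needed for the
  estimators implemented), and comorbidity flags are taken as given
  rather than derived from diagnosis/prescription code streams.
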