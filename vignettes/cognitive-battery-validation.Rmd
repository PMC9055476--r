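---
title: "Validating a composite cognitive battery: scoring, group comparison, and two- and three-class discrimination"
author: "cogdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a composite cognitive battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogdx)
```

## The problem

Computerized cognitive batteries are used as screening aids for cognitive
impairment: a participant completes a fixed set of brief assessments
(here seven: immediate and delayed recognition, digit-symbol
substitution, a flanker task, a Stroop task, and Trail Making A and B),
and the battery reduces their performance to per-assessment scores and a
single composite. The validation question is how well that composite
separates three severity-ordered diagnostic groups — normal cognition
(NC), mild cognitive impairment (MCI), and dementia — after adjusting
for the demographic structure of the sample.

`cogdx` implements that validation pipeline end to end: normative
scoring, covariate-adjusted group comparison, binary ROC analysis, and
three-class classification from a single score, together with a
calibrated synthetic-cohort generator so that every stage can be
exercised and tested without clinical data.

## Scoring model

Each assessment yields an opaque raw score on its native scale, with the
convention *higher is better and the scale is floored at zero*. Three of
the seven assessments (Stroop, Trails A, Trails B) embed a 30-second
per-trial time-out; a timed-out assessment records no raw score.

Scoring proceeds per participant:

1. **Time-out penalty.** Timed-out assessments are scored zero *on the
   raw scale*. The penalty must be imposed before standardization:
   a z-score of zero would denote normative-average performance, which
   cannot act as a penalty. Zero on a floored raw scale is the natural
   worst case.
2. **Per-assessment standardization.** Each raw score is converted to a
   z-score, `(raw − mean) / sd`, against a normative reference entry
   resolved by the participant's age band and test device (iPad versus
   touchscreen computer): performance norms drift with age and differ by
   input device, so both stratify the reference.
3. **Battery composite.** The overall raw score is the arithmetic mean
   of the (penalized) raw scores; assessments missing without a time-out
   are excluded from the mean and flagged with a warning. The composite
   is then standardized against the reference's `"overall"` entry,
   giving the *normalized overall score* — standard-normal in a
   normative population, lower meaning more impaired.

Whether a deployed battery averages raw or per-assessment-standardized
scores before the final standardization is an internal detail of such
instruments; `cogdx` fixes the raw-scale convention above and documents
it, because the choice changes how deeply a time-out drags the
composite. Age bands are half-open `[lo, hi)`; ages outside the covered
range clamp to the nearest band with a warning so that scoring is total.

## Covariate-adjusted group comparison

Every outcome (each assessment z-score, the normalized overall score,
and the battery duration in minutes) is modeled by ordinary least
squares on diagnosis (3-level factor), age (linear), sex, and
administration type (on-site versus remote). Group effects are
summarized as **estimated marginal means** (EMMs): predictions per
diagnosis group with age at its sample mean and sex and administration
averaged with *equal weights* over their levels. Equal factor weighting
is the standard reference-grid convention for adjusted group means; the
EMM machinery is delegated to the `emmeans` package behind this
package's interface, and the test suite cross-checks it against direct
studentized-range and linear-algebra computations.

Pairwise group differences are reported more-severe minus less-severe
(dementia − NC, dementia − MCI, MCI − NC), so the three estimates
satisfy the exact identity
`(dem − NC) = (dem − MCI) + (MCI − NC)`. P-values use the Tukey
(studentized-range) adjustment with 3 means and the model's residual
degrees of freedom, applied within each outcome's three contrasts only —
adjusting across outcomes would change the published-table semantics the
pipeline mirrors.

Two further conventions matter for reproducibility:

* **IQR outlier filtering** (fences `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`,
  quartiles by linear interpolation, `quantile` type 7) is applied per
  assessment to the normalized assessment scores before their model
  fits. It is *not* applied to overall-score, duration, ROC, or
  three-class analyses: outlier trimming is defensible for noisy single
  tasks but would bias discrimination metrics whose business is exactly
  the tails. The type-7 rule makes degenerate cases reproducible, e.g.
  `iqr_filter(c(0,0,0,0,10))` drops the 10 because both quartiles are 0.
* **Demographics tests**: age by one-way ANOVA across the three groups;
  sex, education, and administration by Pearson chi-square on the full
  contingency table, with the "NA" education response kept as its own
  category rather than treated as missing.

## Binary ROC analysis

For each severity-ordered pair the more severe group are the cases, and
the positivity rule is fixed as *score ≤ threshold → positive*. The AUC
is the Mann–Whitney estimator `P(case < control) + ½·P(tie)`, identical
to the trapezoidal area under the empirical curve (asserted to 1e−12 in
the tests). The reported operating point maximizes Youden's
J = sensitivity + specificity − 1; when several cutoffs tie, the one
with higher specificity and then the lower threshold wins, so output is
deterministic. Youden's J is the standard single-number operating rule
when no cost ratio is specified.

## Three-class classification

A single score line is cut twice, `t− ≤ t+`: predict dementia for
`score ≤ t−`, MCI for `t− < score ≤ t+`, NC for `score > t+`
(left-closed on the severe side). Two quantities summarize three-class
performance:

* **VUS**, the volume under the three-class ROC surface: the
  probability that a random (dementia, MCI, NC) score triple is
  correctly ordered, with tie credits extending the Mann–Whitney
  convention to triples — 1 for a strict ordering, ½ when exactly one
  adjacent pair ties, ⅙ for a triple tie. Chance level is 1/6; perfect
  separation gives 1.
* **Optimal cutoff pair**: exhaustive search over candidate cutoffs at
  midpoints between adjacent distinct pooled scores plus ±∞ sentinels —
  a grid that is provably sufficient for empirical distributions —
  maximizing the *unweighted sum of the three group-wise true positive
  rates* (the generalized-Youden objective of the three-class ROC
  framework). A prevalence-weighted variant (overall accuracy) is
  available via `objective = "weighted"` since "diagnostic accuracy" is
  ambiguous between the two. Objective ties break toward the widest
  `t+ − t−` margin, then the smallest `t−`.

The search is separable in the two cutoffs but is implemented as a full
grid evaluation for transparency; tests require exact agreement with
brute-force enumeration on hundreds of random instances.

## The synthetic cohort generator

`calibrated_defaults()` encodes the study conditions the pipeline is
meant to operate under: 99 participants (35 NC / 22 MCI / 42 dementia)
with group-specific age distributions (means 67.8/73.5/71.5 years, SDs
9.6/5.9/9.0), sex (71%/36%/38% female), education, and administration
(17%/27%/31% remote) margins; per-assessment group mean shifts on the
normative z scale equal to the reference EMMs; and individual-level SDs
reconstructed as SE·√n from the reported standard errors (averaged over
groups, since the generator takes one SD per assessment). That
reconstruction ignores the covariate adjustment baked into reported
SEs; it is the only route to a calibrated generator from summary
statistics and is treated as an approximation throughout.

Structural choices, each made once:

* **Shared ability factor.** Within a participant, assessment residuals
  share a general-ability component with intraclass correlation
  `icc = 0.6`. Cognitive scores are strongly positively correlated
  within person; without this the seven-assessment composite would be
  implausibly tight relative to the per-assessment spreads.
* **Dementia heavy tail.** A contaminated normal: a fraction 0.15 of
  dementia participants receive an extra −1.5 z shift and a 1.8×
  SD inflation, reproducing the long left tails impaired samples show
  without committing to a specific heavy-tailed family.
* **Time-outs.** Only Stroop/Trails A/Trails B can time out, with
  per-assessment group rates 0.05 (NC), 0.20 (MCI), 0.45 (dementia) —
  a strong severity gradient consistent with mostly-complete NC testing.
  A time-out is drawn as the *lowest-quantile latent residual* rather
  than an independent coin flip: time-outs arise from response delays by
  participants attempting the task, so they should censor the worst
  latent performances. The marginal rate is still exactly the configured
  probability. A timed-out assessment records no raw score; the scoring
  stage supplies the penalty.
* **Durations.** Battery durations are log-normal with group medians
  17.8/21.5/30.5 minutes and log-SDs matched to the corresponding
  interquartile ranges; per-assessment durations are decorative.
* **Device.** 15% computer, 85% iPad, independent of group — remote
  testing allowed either device and on-site testing used iPads, and the
  normative reference is device-complete either way.

### Calibration of the overall score

The average of the per-assessment z shifts is far smaller than the
reported overall-score separations; in real batteries the gap comes from
raw-scale averaging and from time-out penalties. The generator closes it
exactly: with per-assessment normative entries `(m, s)` shared across
assessments and an overall entry `(μ_o, σ_o)`, the expected group mean
of the normalized overall score is linear in three constants — the
offset `c0 = (m − μ_o)/σ_o`, the per-assessment weight
`w = s/(7 σ_o)`, and the penalty depth `r = m/s` (a timed-out
assessment scores z = −r). Accounting for time-out censoring (the
retained residual mean gains `σ·φ(Φ⁻¹(p))`) and the contaminated tail,
the three group means give a 3×3 linear system in `(c0, w, w·r)`, solved
at construction time so that the expected group means equal
0.71 / −2.15 / −5.63 exactly. The solved constants are attached to the
config as the `"calibration"` attribute; 40-replicate Monte Carlo
during development confirmed the means are recovered to within Monte
Carlo error (≈0.02–0.04).

### What the generator does and does not emulate

It reproduces first moments (demographic margins, per-assessment and
overall group means), a severity-graded time-out process, heavy dementia
tails, and duration scales. It does not reproduce the reported
group-level SDs of the overall score exactly (the penalty mixture
inflates dementia variance beyond the SE·√n reconstruction), does not
model age or device effects on performance within group, item-level
responses, practice effects, or diagnostic misclassification. Passing
tests on synthetic cohorts therefore demonstrates that the *pipeline*
is correct and that the calibrated separations are recoverable — not
that any particular instrument achieves them in the clinic; pairwise
AUCs on synthetic cohorts (≈0.9 for dementia vs NC, ≈0.7–0.75 for the
MCI pairs) are somewhat below clinically reported values because the
variance reconstruction is conservative.

## Numerical and degenerate-input conventions

* Quantiles: linear interpolation (type 7) everywhere.
* Age bands: half-open `[lo, hi)`, clamped at the range ends with a
  warning.
* ROC curves are swept threshold-ascending from (0,0) to (1,1) so both
  coordinates are nondecreasing.
* Cutoff ties: binary — higher specificity then lower threshold;
  three-class — wider margin then smaller `t−`.
* All-identical three-class groups yield objective 1 via a sentinel
  pair (one class fully captured), the exact optimum.
* Constant outcomes fit with zero residual variance: estimates are 0 and
  p-values are undefined (`NaN`), which is surfaced rather than masked.
* Generated cohorts are pure functions of their config (seed included);
  the generator restores the caller's RNG state.

## Problem sizes used by the test suite

Unit and property tests run on instances of ≤ 40 observations with
brute-force oracles (triple enumeration for VUS, full-grid scans for
cutoff searches, pair enumeration for AUC). Distributional checks use
200 seeded replicates at the 99-participant study size (familywise
error under the zero-effect generator ≤ 0.07; VUS exchangeability
within 1/6 ± 0.02 at 200 per group) and a single 20× cohort
(1,980 participants) for parameter recovery within 2 standard errors.
These sizes were chosen to make the stochastic assertions sharp while
keeping the default suite fast.

## Known limitations

* The normative reference shipped by the calibrated config is a
  synthetic single-band stand-in; real deployments should supply their
  instrument's normative table via `read_normative_reference()`.
* EMM factor weighting is fixed at equal weights; proportional
  weighting would change EMMs (not contrasts of a balanced factor) and
  is intentionally not exposed.
* The IQR-filter scope (per-assessment fits only) is a documented
  modeling decision; filtered and unfiltered runs are both one flag
  away in `run_pipeline()`.
* Three-class confidence intervals (e.g., bootstrap bands for VUS) are
  out of scope.
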