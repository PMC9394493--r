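---
title: "Dynamic landmark prediction of recruit attrition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic landmark prediction of recruit attrition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitrisk)
```

## The problem

Roughly half of the recruits entering a 24-week military basic-training
programme leave before completing it, about a quarter of them because of
musculoskeletal problems, and most of the remainder at their own request.
Baseline anthropometrics and fitness scores predict some of this risk, but
factors such as motivation, sleep quality and perceived fitness fluctuate
from week to week, so a model that uses only enlistment-day information
ignores exactly the signals that weekly self-report monitoring collects.
`recruitrisk` implements a dynamically updated prediction pipeline: a
landmarking Cox supermodel over weekly landmarks that combines fixed
baseline covariates with the latest weekly self-reported health status, and
re-expresses each recruit's risk as a conditional probability of dropping
out in the coming week(s) given survival so far.

Because recruit-monitoring databases of this kind are not publicly
deposited, the package pairs the analysis pipeline with a synthetic cohort
generator that emulates the published cohort conditions. Every stage of
the pipeline is therefore testable offline, including against the
generator's own truth records.

## The supermodel

Landmarks are placed at the end of each training week, at days
$7s,\ s = 1,\dots,S$ with $S = \text{weeks} - 1 = 23$, each with a one-week
prediction window $(7s,\ 7(s+1)]$. At landmark $s$ the risk set contains
every recruit still in training at day $7s$ whose covariates have been
observed by week $s$. Stacking the 23 landmark datasets gives the
supermodel, whose hazard for recruit $i$ is

$$h(t \mid Z_i(s), s) = h_0(t)\,
  \exp\!\big(Z_i(s)\,(\beta_1 + \beta_2\,\mathrm{code}(s)) + X_i \gamma\big),$$

with $X_i$ the nine baseline terms (height, body mass, age, two education
dummies against the "unknown" reference, body-fat percentage, Cooper
distance, push-ups and sit-ups per 10 repetitions), $Z_i(s)$ the six
time-varying terms (five Likert items plus the dichotomized pain
indicator), and $\beta_2$ the landmark interactions that let the
time-varying effects drift across landmarks. The partial likelihood is
maximised by `survival::coxph()` on counting-process intervals
$(\text{start}, \text{stop}]$ = $(7s, \min(\text{event day}, 7(s+1))]$,
which confines each row's risk contribution to its own window; tests verify
the estimates against brute-force maximisation of the explicitly written
partial likelihood on tiny instances.

**Interaction coding.** The published worked example computes the
motivation effect at the first landmark as $\beta_1$ alone and adds one
interaction increment per subsequent landmark, which corresponds to
$\mathrm{code}(s) = s - 1$; the methods formula as written reads
$\mathrm{code}(s) = s$. Both codings are offered
(`landmark_coding = "s_minus_1"` or `"s"`); the default is `"s_minus_1"`,
which reproduces the worked example ($-0.42$ at $s=1$ updating to $-0.40$
at $s=2$ for a one-point motivation advantage). The discrepancy is a
documentation ambiguity of the source analysis, not something the data can
resolve, so both remain available.

**Centering and the reference subject.** All design columns are centred at
a fixed reference subject (23 years, 1.80 m, 80 kg, 14% body fat, 2.8 km
Cooper, 55 push-ups, 55 sit-ups, unknown education, neutral Likert score 5,
no pain), so the linear predictor of the reference subject is exactly zero
at every landmark and the Breslow baseline hazard
$\hat H_0$ is the reference subject's cumulative hazard. Conditional
dropout probabilities follow as
$1 - \exp\{-(\hat H_0(7(s{+}h)) - \hat H_0(7s))\,e^{LP(s)}\}$.

**Ties and variance.** Breslow tie handling is the default (Efron via
config); with one-week windows and day-resolution event times ties are few.
Model-based variance is the default: the nonoverlapping windows make a
recruit's window contributions conditionally independent given the
landmark covariates. A recruit-clustered sandwich (`variance = "robust"`)
is available since one recruit still spans many stacked rows. Rubin
pooling (`pool_rubin()`) is provided for multiply imputed runs, but the
pipeline's imputation is single (mean imputation + LOCF), so the default
is the vacuous $m = 1$ case.

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs:

* **Baseline covariates** are independent truncated normals matching the
  published cohort means and SDs (body mass 77.9 ± 7.9 kg, Cooper
  2.87 ± 0.158 km, ...), truncated to the eligibility limits (height ≥
  1.65 m, mass ≥ 65 kg, Cooper ≥ 2.7 km, ≥ 30 push-ups and sit-ups, age
  17.5–27.9 y). The pre-truncation mean of each covariate is re-solved by
  root finding so the *realised* truncated mean equals the published mean.
  Two published SDs (height "6.4", Cooper "1.58") are dimensionally
  inconsistent with their eligibility bounds and are read as the obvious
  misprints 0.064 m and 0.158 km. Education is drawn with probabilities
  0.25/0.17/0.58 (level 1 / level 2 / unknown). Marginals only are
  published, so independence is the default; a correlation structure was
  considered and omitted as unidentifiable from the source.
* **Weekly Likert trajectories** are stationary AR(1) series around
  recruit-level item intercepts (population mean 7, between-recruit SD 1,
  AR coefficient 0.6, innovation SD 0.8), discretised to 1–10 by clamped
  rounding. These values are the package's choice of a realistic weekly
  self-report process — positively-phrased items cluster high with
  moderate week-to-week persistence — and are fixed once; nothing in the
  published tables constrains them directly.
* **Pain reports** arrive as weekly Bernoulli events (default probability
  0.01, reflecting the remark that self-reported injuries were remarkably
  few) with an NPRS severity drawn 1–10.
* **Dropout** follows the supermodel's own hazard class: in calendar week
  $w \ge 2$ the weekly hazard is
  $h_w = h_{0,w}\, e^{Z(s)(\beta_1+\beta_2\,\mathrm{code}(s)) + X\gamma}$
  with $s = w - 1$ — exactly the covariates and coding the landmark model
  sees for events in window $s$ — and the dropout day is uniform within
  the week. Week-1 events, which precede the first landmark and are
  excluded from estimation, use the week-1 values. The true coefficients
  default to the logs of the published hazard ratios.
* **The weekly base hazard** is geometric, $h_{0,w} = a\,r^{w-1}$, with
  $(a, r)$ calibrated once by nested root finding on the exact
  expected-dropout equations over a fixed 40,000-recruit covariate
  population so that 54.8% of recruits drop out within 24 weeks and 22% of
  dropouts occur in the first four weeks. The calibrated pair
  ($a = 0.08282,\ r = 0.98736$) ships as the default;
  `analysis/00_calibrate_hazard.R` re-derives it.
* **Dropout reasons** are drawn from the published mixture 137/240/27
  (injury / individual request / other; these sum to 404 of the 408
  dropouts — the remainder presumably the never-tabulated "military
  competences" category — so the mixture is normalised over 404). The
  injury weight is multiplied by 3 (configurable) for recruits with a pain
  report by their dropout week; whether injury-reason dropout requires a
  prior pain report is not stated in the source, so the link strength is a
  free parameter. Exit surveys are generated for dropouts only, with item
  means tied to the true reason so the ≥ 7 agreement rule is testable.
* **Missingness** reproduces the observed pattern: 8% of recruits with at
  least one missing baseline field; 4% left-truncated (first 1–3 status
  weeks deleted); 1.4% of the cohort week-1 dropouts with all status rows
  erased (implemented by masking actual simulated week-1 dropouts so the
  truth record stays consistent); and the mental-fitness item erased
  missing-not-at-random, with erasure probability increasing in
  $(10 - \text{latent value})$ and the intercept solved so the overall
  missing fraction is 61%.

What the generator does **not** emulate: correlated baseline covariates,
sporadic interior gaps in the non-mental-fitness items (the study
quantified only the patterns above, so LOCF's gap-filling path is
exercised by constructed cases in the tests rather than by the default
cohort), seasonal or cohort effects, re-enlistment, and female recruits
(the source sample is all male). Passing tests therefore show that the
pipeline correctly estimates and evaluates the model class the study
assumes — not that the model is correct for any particular real cohort.

All randomness flows from one master seed through named streams (one per
sub-generator, derived by hashing the stream name into the seed), so
enabling or reconfiguring one stream — e.g. missingness — never perturbs
another, and a fixed seed reproduces a cohort byte-identically.

## Preprocessing rules

* Continuous baseline covariates are mean-imputed (observed-column means);
  education is never imputed — "unknown" is its own (reference) level.
* Weekly items are completed by LOCF within recruit; weeks before the
  first observation remain unavailable, and the affected recruit enters
  the risk sets only from the first observed week (left truncation). A
  recruit whose dropout precedes any observation is excluded.
* The pain indicator is dichotomized ("any location marked that week") and
  then carried as an absorbing ever-injured state — the literal reading of
  the retention rule; `pain_carry = "locf"` preserves the alternative.
* Items are screened on the raw (pre-LOCF) table: dropped when the missing
  fraction exceeds 0.5 or the observed variance falls below $10^{-3}$
  (strict inequalities). Under the default missingness the mental-fitness
  item (61% missing) is dropped, leaving the 21 predictors of the final
  model.

## Evaluation

The incident/dynamic AUC at day $t$ is implemented exactly as its
pairwise definition: cases are dropouts with event day within ±7 days of
$t$ (the two-week smoothing window), scored at their latest landmark
before the event; controls are recruits still in training beyond $t + 7$,
scored at the latest landmark at or before $t$; ties count one half. A
rank-sum implementation is used in production and the definitional double
loop is the test oracle. No inverse-probability-of-censoring weights are
applied: windows are one week and censoring is administrative at day 168.
ROC curves sweep all distinct score thresholds; the operating threshold
maximises Youden's $J$ with ties broken toward higher specificity.
Evaluation starts at day 7 — events before the first landmark cannot be
scored (their covariates were never seen), matching the source's exclusion
of the ten earliest dropouts.

Cross-validation is repeated stratified 10-fold CV on *recruits* (never on
stacked rows, which would leak a recruit's other landmarks into training),
with out-of-fold linear predictors assembled per repeat and percentile
bands over repeats. A training split without events is resampled and
flagged. The figure caption of the source mentions "bootstrap"
cross-validation; the procedure described in its text — repeated 10-fold
CV — is what is implemented. The source's 500 repeats remain available via
configuration; the analysis scripts default to 20, which stabilises the
mean AUC(t) to well under the width of its percentile band at this sample
size.

The baseline-only comparison model is a conventional Cox fit on the nine
baseline covariates from day 0, with no landmarking; left truncation does
not apply to it because baseline covariates are known at enlistment.

## Numerical choices and degenerate inputs

* Partial-likelihood convergence: `coxph` with tolerance $10^{-9}$, 100
  iterations maximum; constant design columns are rejected before fitting,
  and a non-unique maximum (NA coefficients) raises an error.
* Truncated-normal sampling by inverse CDF; infeasible truncation (target
  mean at or outside the bounds, or negligible mass) raises an error.
* The MNAR intercept and the calibration roots are solved by `uniroot` to
  tolerances of $10^{-10}$ or better.
* Zero base hazard yields an all-censored cohort; `n_recruits = 0` yields
  empty tables from the generator and a clean error from the pipeline.
* An AUC evaluation with no cases or no controls is reported as missing
  (`NA`), not an error.

## Problem sizes used by the tests

The test suite runs the full estimation chain at reduced but informative
sizes, chosen once as adequate for their Monte-Carlo tolerances: cohorts of
150–300 recruits for structural checks; a single 5,000-recruit cohort for
the motivation-effect recovery; 50 cohorts of 1,000 for the bias and
coverage sweep of all 21 coefficients; 20 cohorts of 744 for the
calibration targets; 10 cohorts of 2,000 for the supermodel-vs-baseline
comparison; 200 outcome permutations for the no-signal AUC check.

## Known limitations

* The generator samples baseline covariates independently; real
  anthropometric and fitness measures correlate, so real-data AUCs need
  not match synthetic ones.
* LOCF and mean imputation are the source's choices and are reproduced
  faithfully; neither is a principled missing-data model, and the MNAR
  mechanism the generator builds into the mental-fitness item is exactly
  the kind of process LOCF cannot repair — the pipeline handles it the way
  the source did, by screening the item out.
* The published headline AUCs (0.78/0.75/0.73) and hazard ratios were
  estimated on the original, non-deposited military cohort; they serve
  here as generator defaults and plausibility bands, not as reproduction
  targets.
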