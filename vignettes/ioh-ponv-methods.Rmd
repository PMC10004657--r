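---
title: "Methods: characterizing intraoperative hypotension and estimating its association with PONV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing intraoperative hypotension and estimating its association with PONV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(iohponv)
```

## Overview

`iohponv` implements a two-aim analysis of intraoperative hypotension
(IOH) and postoperative nausea and vomiting (PONV) for cohorts in which
one patient may contribute several surgeries. The pipeline runs:
blood-pressure artifact removal → uniform 15-s mean-arterial-pressure
(MAP) gridding → a family of scalar IOH characterizations → marginal
logistic (GEE) models with spline bases → cluster-respecting repeated
cross-validation and Brier-score model selection on a *shaping* half of
the cohort → adjusted odds-ratio estimation on the independent
*estimation* half. A synthetic-cohort generator with known ground truth
supports all testing.

This vignette records the statistical model, the tunable parameters and
their defaults, the numerical choices, and the design decisions taken
where more than one reasonable implementation existed.

## Preprocessing

**Artifact rules.** Six classifications, applied per surgery: (1)
SBP ≥ 300 mmHg, (2) SBP ≤ 20 mmHg, (3) DBP ≤ 5 mmHg, (4)
DBP ≥ 225 mmHg, (5) SBP ≤ DBP + 5 mmHg, (6) values outside three
standard deviations of the record's mean pressure. Rules 1–5 are
pointwise predicates on the raw channels and are therefore idempotent
and order-independent. Rule 6 runs once, after rules 1–5, per channel
(SBP, DBP, MAP — any hit removes the sample), against the mean and SD of
the samples that survived rules 1–5.

Two choices deserve note. First, rule 6 is scoped *per surgery*, not
pooled across a patient's admissions: surgeries are processed
independently, and pooling across records taken months apart would mix
different physiological baselines. Second, the rule-6 reference moments
are computed *leave-one-out*: each sample is compared with the mean ± 3
SD of the other surviving samples. On records of realistic length
(hundreds to thousands of samples) this is numerically indistinguishable
from the pooled version; on short records it matters, because a lone
extreme value inflates the pooled SD enough to mask itself — the largest
attainable z-score in a pool of n values is (n−1)/√n, below 3 for
n ≤ 10. Leave-one-out removes this blind spot without iterating the rule
to convergence (which would be a different, trimming-style procedure).

**MAP derivation.** The recorded MAP is preferred where present —
oscillometric monitors measure MAP directly and *compute* the systolic
and diastolic values — otherwise MAP = DBP + (SBP − DBP)/3.

**Gridding.** Clean MAP is interpolated linearly to t = 0, 15, 30, … s.
Outside the observed span the nearest observed value is held constant:
extrapolating a trend before the first cuff reading could manufacture
hypotension that was never measured. Cases with fewer than two usable
samples are flagged unusable and excluded, with accounting. Each grid
point represents the half-open interval [t, t + 15 s), so all
time-under accounting is (number of points) × 0.25 min. Intra-operative
gaps of any length are bridged linearly; we do not censor long gaps
(the alternative is noted as future work — real records rarely pause
monitoring for long).

## Characterizations

Four families, 24 members, all computed from the gridded MAP:

* `sustained_lowest_k` (k ∈ 1, 3, 5, 10, 15 min): the lowest ceiling
  under which MAP stayed for k *contiguous* minutes — the minimum over
  all windows of exactly k·60/15 + 1 grid points (inclusive endpoints
  span exactly k minutes) of the window maximum. Scanning longer windows
  cannot lower a window maximum, so exact-length windows suffice.
* `cumulative_lowest_k`: the lowest ceiling under which MAP spent at
  least k total minutes, contiguous or not — the m-th smallest grid
  value with m = ⌈k·60/15⌉.
* `time_under_θ` (θ ∈ 50, …, 80 mmHg): minutes with MAP strictly below
  θ. "Under" is strict `<` throughout the package; the sustained and
  cumulative families use `≤` ("stayed at or below its ceiling"), which
  makes the duality exact: time_under(θ) ≥ k minutes ⟺
  cumulative_lowest(k) < θ, for θ not equal to a grid value.
* `fraction_under_θ`: time_under divided by the gridded record span
  (the record span is our proxy for the duration of anesthesia).

A grid shorter than k minutes yields an undefined (missing) value for
the k-minute families; such cases drop out of that characterization's
model only.

## The outcome model

For each characterization, PONV is modelled by a marginal logistic
regression fitted with generalized estimating equations (GEE), patient
as the clustering variable, exchangeable working correlation, and
robust (sandwich) standard errors. The linear predictor contains:

* the exposure, winsorized at the empirical 99th percentile and
  represented by a natural cubic spline basis with 3 degrees of freedom;
* for the time/fraction families, an indicator that the exposure is
  exactly zero (these exposures have a large point mass at zero; the
  indicator absorbs it so the spline models only the continuous part).
  The indicator enters only when the fitting data actually contain
  zeros — an all-zero indicator column is unidentifiable — and the
  decision is stored with the fitted bases;
* confounder main effects: sex, smoking status, volatile anesthetics,
  ondansetron prophylaxis, dexamethasone prophylaxis, positive Charlson
  comorbidity score, high-PONV-risk surgery type;
* ASA status as three dummies against ASA 1;
* age and surgery duration, each as a 3-df natural spline;
* the age-by-sex interaction, realized as the three age-spline columns
  multiplied by the female indicator.

Postoperative opioid use is deliberately **not** a covariate: it occurs
after the exposure and adjusting for it would condition on a
post-exposure variable. It enters only the Apfel score convenience
function, which is reporting-only.

**Spline knots.** Boundary knots sit at the observed minimum and
maximum, interior knots at the 33.3rd and 66.7th percentiles (of the
*nonzero* values for zero-inflated exposures). With fewer than four
distinct values the basis degrades to a single linear term with a
warning. Knots and winsorization caps are part of the fit artifact and
are re-used verbatim when the design is rebuilt on held-out data; age
and duration knots are re-derived per fitting dataset rather than shared
across models.

**GEE numerics.** The exchangeable inverse has the closed form
R⁻¹ = I/(1−α) − α J/((1−α)(1+(n_i−1)α)), so scoring, the working
correlation update (moment estimator on Pearson residuals, α clamped to
(−1/(max n_i − 1), 0.99)) and the sandwich are computed from cluster
sums without per-cluster inversion. Fisher scoring uses step-halving on
the estimating-equation norm — plain scoring diverges under
quasi-separation — with convergence declared at a relative coefficient
change below 1e-6, at most 60 iterations, and a hard divergence guard at
|β| > 1000. Non-convergent models are flagged and excluded from
comparisons, never silently retained. When every cluster has size one
the fit reduces to ordinary logistic regression (verified to 1e-6 in the
tests). No penalization is used anywhere.

A practical consequence of the 24-column design: fits need roughly five
events per parameter to be reliably identified. The default simulated
cohort (1,500 patients, ~2,050 surgeries, ~10% PONV) gives each split
arm ~125 events and fits stably; substantially smaller cohorts produce
quasi-separated, formally non-convergent fits, which the pipeline
reports rather than hides.

## Cross-validation and model selection

Folds are assigned to *patients*, never to surgeries, so a patient's
procedures stay together; folds are balanced to within one patient. The
full protocol is 10 folds × 40 repetitions; the package default for
routine runs is 5 × 5, with the full protocol one config edit away.

Within each training fold the winsorization cap and all spline knots are
re-derived from that fold's data only, preventing leakage from held-out
cases (the alternative — freezing caps and knots from the full shaping
set — is noted as a config-level variation; we chose strict re-derivation
as the conservative default). Held-out predictions are pooled within a
repetition, the four metrics (Brier score, c-statistic, discrimination
slope, calibration slope) are computed on the pooled set, and means and
SDs are taken across repetitions (pool-then-average; with a single
repetition the SD is reported as 0 by convention). Folds whose model
fails — single-class training outcome or non-convergence — are dropped
from their repetition with accounting.

The best characterization is the one whose model attains the smallest
mean cross-validated Brier score; ties break by higher c-statistic, then
label order, and the tie-break is recorded. All 24 characterizations are
implemented and the candidate set is configurable; analyses that
historically fitted 23 models can reproduce that by listing their 23.

**Variable contributions.** For the selected model, each variable group
(exposure; sex; age; smoker; volatile; ondansetron; dexamethasone; the
ASA block; comorbidity; risk surgery; the duration block) is omitted in
turn and the model re-cross-validated on the identical fold plan; the
increase in Brier score over the full model measures that variable's
contribution. Omitting sex or age also omits the age-by-sex interaction.

## Split-sample estimation

Patients are randomly allocated — with all their surgeries — to the
shaping or the estimation arm, greedily targeting equal procedure
counts (arm sizes differ by at most the largest single patient's
procedure count). Selection runs only on the shaping arm; the adjusted
OR is estimated only on the estimation arm, so the estimate is untouched
by the multiple comparisons of step 1.

The OR contrast between exposure x and the zero-exposure reference
("MAP consistently above the threshold") is
log OR = [s(x) − s(0)]·β_spline − β_zero-indicator (for zero-inflated
families), with variance by the delta method through the robust
covariance — exact here, since the contrast is linear in the
coefficients. x beyond the winsorization cap is evaluated at the cap
with a note. Because a spline dose-response typically rises and then
flattens, the package exposes OR-at-x for any x rather than hard-coding
a landmark, and `or_curve()` reports the first x at which the spline's
log-odds derivative drops below a tolerance (default 0.01 per exposure
unit) — the plateau point. The default contrast point in
`run_full_analysis` is the median positive exposure of the estimation
arm.

## The synthetic cohort generator

The generator exists so that every stage has a test bed with known
truth; it emulates the statistical structure the analysis assumes, not
operating-room physiology.

* **MAP process**: a discretized mean-reverting (AR(1)/OU) process with
  exact transitions over arbitrary sampling gaps, stationary SD
  `noise_sd`, plus an exponentially decaying induction dip in the first
  ~10 minutes. Closed-form stationary moments make trace-level oracle
  tests exact. Defaults (baseline 79 mmHg, dip 13 mmHg with 3-min decay,
  reversion 0.3/min, stationary SD 9.5 mmHg) were chosen once so that
  the implied exposure distributions sit at the scale reported for large
  perioperative cohorts (median lowest 1-min MAP ≈ 61 mmHg, median time
  under 65 mmHg ≈ 6 min, ~10% of surgeries with any MAP below 50 mmHg);
  they are working defaults, not calibration targets.
* **Sampling**: invasive monitoring every 15 s (20% of cases by
  default), oscillometric cuffs at uniformly random 3–5-min intervals
  (80%), matching the roughly 80% non-invasive mix of routine practice.
* **Pressures**: pulse pressure is log-normal (median 45 mmHg), with
  SBP = MAP + 2PP/3 and DBP = MAP − PP/3, so the recorded MAP satisfies
  the MAP formula exactly and rule-5 filtering is exercised
  meaningfully.
* **Artifacts**: injected at a configurable rate per hour, each sample
  violating exactly one of rules 1–5 or being an extreme deviation
  aimed at rule 6, with ground-truth labels returned.
* **Cohort structure**: surgeries per patient ~ 1 + Poisson(rate − 1)
  with rate 1.37 (≈ the 38.6k surgeries / 28.3k patients ratio of large
  single-center cohorts); covariate marginals approximate a general
  surgical population (54.5% female, age ~ N(53, 17) truncated at 18,
  32.5% smokers, ASA 1–4 at 48/26/24/2%, 64% volatile anesthesia, 17.7%
  risk surgery, 15.3% PONV history) — approximations, not targets.
* **Outcome**: log-odds = intercept + confounder terms +
  β_nonzero·1[exposure > 0] + β_per-unit·exposure + patient random
  intercept (Normal, SD 0.5), with the exposure computed from the case's
  own clean gridded trace by the characterization module — so the stored
  truth is *exactly* reproducible from the stored grids, and the
  generator and the feature module can never drift apart. Default effect
  (β_nonzero 0.25, β_per-unit 0.02/min on time-under-50) corresponds to
  an OR of ~1.3 for ~2 minutes under 50 mmHg, the scale reported for
  this association; the default intercept −2.9 yields a ~10–12% PONV
  rate.

Because the generator draws a *conditional* (random-intercept) model and
the GEE estimates a *population-averaged* one, recovery tests compare
against the marginalized contrast, computed exactly by numerically
integrating the random intercept out at the cohort's baseline linear
predictors (the classical 1/√(1 + 0.346σ²) attenuation factor is a
cruder approximation, off by ~0.005 at these settings).

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: treatment feedback
(vasopressors or fluids given *because* pressure fell), informative
monitoring gaps, measurement error correlated with the outcome,
between-hospital heterogeneity, and any baseline-pressure-relative
exposure definition (preoperative baselines are not simulated).

## Problem sizes and determinism

Routine runs and the acceptance script use the default configuration:
1,500 patients (~2,050 surgeries), eight candidate characterizations,
5-fold × 5-repetition cross-validation, and the full contribution
analysis — a few minutes of single-core compute chosen so the whole
pipeline, including its simulation-based checks, runs comfortably on a
laptop. The simulation studies in the test suite use 100 cohorts of
1,000 patients (parameter recovery) and 20 cohorts of 1,500 patients
(selection consistency). All randomness flows from explicit integer
seeds; a configuration re-run reproduces its report bundle byte for
byte.

## Known limitations

* The exchangeable working correlation is a modelling convenience; the
  sandwich covariance protects the inference against its
  misspecification, but small numbers of multi-surgery patients make α
  noisy.
* Spline log-OR contrasts on zero-inflated exposures are
  high-variance at moderate cohort sizes; confidence intervals are wide
  and honest.
* Rule 6's per-surgery scope cannot detect a whole record that is
  systematically offset.
* The univariate association screen is provided only as a convenience
  (fit the model with the exposure as sole covariate block); it is not
  part of the selection pathway.
* Winsorization caps learned on small training folds are order
  statistics of small samples and therefore variable; this is inherent
  to strict per-fold re-derivation.
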