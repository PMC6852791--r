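---
title: "Evaluating a team-based diabetes program with targeted learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a team-based diabetes program with targeted learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diabtmle)
```

## Setting and estimand

The package evaluates a multidisciplinary diabetes care program
(DIABETIMSS) on a binary outcome, glycemic control, using serial
cross-sectional electronic health records: up to five yearly snapshots per
patient, from six clinics delivering the program and five delivering
conventional care. Exposure `A` is attendance of the program at least once
in the year; the outcome `Y` is control at year end, determined directly by
the latest HbA1c of the year (< 7%) or, failing an HbA1c, inferred from the
last three fasting plasma glucose measurements of the year (all
≤ 130 mg/dl). With fewer than three glucose values and no HbA1c the outcome
is undetermined; when both rules apply and disagree the HbA1c verdict wins
and the record is flagged (the disagreement rate is worth inspecting in any
new data source).

The estimand is the average treatment effect on the risk-difference scale,
`ψ = E_W[Q(1, W) − Q(0, W)]` with `Q(a, w) = P(Y = 1 | A = a, W = w)`,
estimated per program clinic (years pooled within clinic) and pooled over
the program clinics by stacking their data with clinic indicator
covariates. Identification assumes no unmeasured confounding given the
recorded covariates, positivity, and — because ~62% of outcomes are
unobserved — missingness at random given `(W, A)`, handled by complete-case
analysis: under MAR the conditional regressions fit on complete cases are
unbiased for the full-population regressions.

Inference treats the patient, not the patient-year, as the independent
unit: influence-curve contributions (or bootstrap resampling units) are
aggregated within patient before variances are taken.

## Data cleaning

Non-plausible laboratory and anthropometry values are removed per value,
never per record, with predefined windows: systolic blood pressure outside
(50, 250) mmHg, diastolic outside (40, 200), height outside (130, 250) cm,
weight outside (30, 200) kg, HbA1c below 3.0%, fasting glucose below
37 mg/dl. The exclusion log records every dropped value with the violated
bound; filtering is idempotent. Outcome derivation sorts each patient-year
series by date internally, so unsorted input is harmless.

## The synthetic cohort

The original patient data are not publicly available, so every downstream
stage is developed and tested against a seeded generator
(`generate_study()`) whose defaults emulate the study's structure:

* six program clinics and five conventional-care clinics, five years,
  with year-one control probabilities among the unexposed anchored at the
  observed clinic baselines (0.36, 0.40, 0.34, 0.31, 0.16, 0.20 for the
  program clinics; 0.33–0.21 for the conventional ones, which the source
  tables do not report and which we set to span a similar range);
* stable patient covariates (sex, age, anthropometry and BMI-derived
  nutrition status and obesity, smoking, risk factors, insurance type,
  complication count), with age advancing yearly;
* prior-year control as a dynamic covariate: year *t*'s
  `previous_control` is the realized outcome of year *t − 1*, the first
  year drawn at the clinic baseline. Its outcome coefficient (1.9 on the
  logit scale) reproduces the study's persistence pattern — about 61% of
  controlled patients stay controlled versus 18% of uncontrolled patients
  achieving control;
* exposure only inside program clinics, assigned by a main-effects
  logistic model on prior control (+), age (−), complications (−) and risk
  factors (+), its intercept calibrated per clinic to a 28% prevalence;
  conventional-care clinics have exposure exactly zero;
* missing outcomes imposed by a logistic MAR model on age, prior control
  and exposure, its intercept calibrated to the 62% target; the model
  never sees the outcome, so missingness is MAR by construction;
* seven process-of-care indicators generated as strongly
  exposure-associated (log-odds 1.0 each), weakly covariate-associated and
  outcome-irrelevant flags. This strength was set so that the two
  documented diagnostic behaviours coexist: adding the indicators to the
  propensity model visibly inflates the near-zero propensity mass (well
  past the positivity flag margin) while the pooled effect estimate moves
  by less than its Monte-Carlo error.

**Treatment-effect construction.** Constant-effect scenarios place the
effect on the logit scale — a single treatment coefficient per clinic-year
calibrated (by root finding on the realized covariate sample) so that the
mean risk difference equals the configured ATE exactly. This keeps the
"original-like" world a *correctly specifiable* main-effects logistic
model, which is what a clean estimator-recovery benchmark requires, while
still fixing the risk-difference estimand exactly. Subgroup-varying
effects (`blip` type `by_complications`) are instead added on the risk
scale, so the true blip is exactly the configured value within each
complication stratum and varies *only* across strata — the designed
heterogeneity is then the sole subgroup signal a partitioning method
should find. Potential-outcome probabilities are clipped to [0.01, 0.99]
and the potential outcomes are drawn with a shared uniform (monotone
coupling).

**Randomness contract.** One master seed; every clinic-year-stage draws
from its own derived substream, so adding clinics or years never perturbs
previously generated records, and all downstream seeds (folds, bootstrap,
simulation replicates) derive from the same integer.

Four built-in scenarios drive the tests: `original-like` (correctly
specifiable, constant 5-point effect), `variant` (the outcome surface adds
a quadratic age term and prior-control-by-complications and
age-by-risk-factor interactions, so a main-effects logistic outcome fit is
misspecified and leaves residual confounding; the exposure model stays
main-effects, so the propensity is correctly specifiable and double
robustness carries TMLE), `null` (no effect *and* randomized exposure, the
scenario in which all three estimators must agree at zero), and `hte`
(effects 0.064 / 0.045 / 0.026 at 0 / 1 / >1 complications, echoing the
observed leaf range).

What the generator does **not** emulate: enrollment and drop-out (every
patient contributes all years), covariate missingness, clinic-level
covariate imbalance (all clinics share one covariate law — deliberately,
since the source data showed overlapping clinic distributions), secular
year trends, correlated process indicators, and informative (MNAR)
missingness. Passing tests therefore demonstrate estimator correctness
under the study's *assumed* structure, not robustness to its violations.

## Super Learner

`fit_super_learner()` stacks candidate learners by V-fold cross-validation
(default V = 10, folds clustered on the patient so repeated years never
straddle a split) under negative Bernoulli log-likelihood, then solves for
convex weights over the simplex using a permutation-equivariant softmax
parametrization (BFGS), with every vertex and the uniform point as
fallback candidates — so the ensemble's CV risk can never exceed the best
single candidate's, and exact ties resolve toward the sparser solution.
Predictions are floored at 1e-6 from both ends to keep the log-loss
finite. A learner that fails on any fold is dropped with a warning; the
fit aborts only if all fail.

The default library — marginal mean, main-effects logistic,
pairwise-interaction logistic, a depth-limited regression tree, and
shallow gradient boosting when xgboost is installed — spans smooth and
non-smooth regression surfaces; the study that motivated this package did
not publish its candidate list, so this library is the package's own
choice (a k-nearest-neighbour candidate is provided but not default: its
prediction cost is quadratic).

## Estimators

*Unadjusted*: group proportions and their difference, binomial-variance
Wald intervals, optional patient-clustered variance.

*Logistic g-computation*: one logistic fit of Y on (A, W); standardized
means are averages of predictions with A forced to 1 and to 0 over all
observed covariate rows. Confidence intervals resample patients (default
500 bootstrap replicates). Coefficients above 15 in absolute value trigger
a separation warning; a singular design is an error. With an empty
adjustment set the model is saturated in A and the estimator reduces
exactly to the unadjusted proportions — a useful identity check.

*TMLE*: initial outcome fit by logistic regression or Super Learner;
propensity by `fit_propensity()` with truncation at [0.025, 0.975]
(distribution diagnostics are logged, and more than 20% of scores at the
bounds raises a positivity warning); the one-dimensional fluctuation
`logit Q* = logit Q⁰ + ε·H` is first fit as a logistic GLM with offset and
then polished by Newton steps until the score `mean(H·(Y − Q*))` is below
1e-13 — this is what makes the efficient influence curve's empirical mean
vanish to machine precision, the estimating-equation property the tests
assert at `|mean(IC)| < 1e-8 · sd(IC)`. Setting `fluctuate = FALSE` forces
ε = 0 and reproduces the plug-in of the initial fit exactly. Standard
errors come from the influence curve with within-patient aggregation.

The pooled estimate stacks the program clinics' rows and adds clinic
indicators to the adjustment set — shared machinery with the per-clinic
path rather than a meta-analytic average. A clinic observed at a single
exposure level is skipped with a warning.

## Heterogeneity

Individual treatment effects (blips) are differences of outcome-model
predictions at A = 1 and A = 0 per covariate row, taken from the
*initial* (machine-learning) fit, not the targeted one: targeting is a
one-parameter marginal correction and has no per-row interpretation. The
engine is configurable; besides the Super Learner and the main-effects
logistic there is `logistic_interactions` — main effects plus
exposure-by-covariate interaction terms, the natural parametric model when
the effect itself may vary, and the engine used for large replicated
sweeps where refitting the full ensemble is disproportionate.

The blip tree is CART (rpart, squared-error splitting) with defaults
complexity 0.01, minimum leaf 20, maximum depth 5, no cross-validated
pruning by default (available behind `cv_prune`). Constant blips collapse
to a single root node. Leaf means are exact member means; the tree's
accounting identities (children partition parents, size-weighted leaf
means reproduce the overall mean) are asserted in the tests.

A caution on power: detecting *which* covariate drives effect
heterogeneity requires estimating exposure-by-covariate interactions,
whose information content is far smaller than the main effect's. Under
the `hte` scenario's designed contrasts (3.8 percentage points between the
extreme complication strata, at 28% exposure prevalence), the first tree
split recovers the complication count reliably only at sample sizes well
above ten thousand patient-years; at 10,000 the recovery rate — reported
by the acceptance computation — is far below certainty. Subgroup findings
at moderate n should be read as exploratory, which is also how the source
study frames its tree.

Predicted program impact in conventional-care clinics routes those
clinics' covariate rows through the tree (or differences the outcome
model) and summarizes per-clinic five-number distributions; tree
predictions are by construction elements of the leaf-mean set. Because
generated clinics share one covariate law, the transported mean impact
matches the program-clinic mean effect — with real data this step carries
the additional assumption that the outcome model transports.

## Simulation study

`run_simulation()` generates a fresh dataset per replicate, applies every
requested estimator to the *same* data (a paired design that sharpens
estimator contrasts), and aggregates bias, empirical SD, mean SE, RMSE
(with `RMSE² = bias² + variance` holding exactly under the
mean-squared-deviation variance) and 95% CI coverage against that
replicate's ground truth. Defaults: 200 replicates of ~2,000 records
(≈ 1,100 program-clinic rows after restriction). Estimation uses the
logistic engines — in the `variant` world the misspecification contrast is
precisely the point, and the correctly specified propensity lets TMLE's
double robustness show while g-computation stays biased. Outcomes enter
the estimators fully observed: under MAR plus complete-case analysis the
conditional models are unbiased anyway, so imposing missingness would only
shrink the effective sample; the missingness contract is tested separately
(a switch re-enables it).

## Diagnostics and sensitivity

Covariate PCA centers and scales to unit variance and reports orthonormal
loadings, non-increasing explained-variance fractions and per-group score
centroids, grouped by clinic or by outcome-missingness status; categorical
covariates must be one-hot encoded by the caller (the package's covariates
are numeric). Zero-variance columns are dropped with a warning.

The propensity comparison summarizes raw (untruncated) scores under the
base and extended adjustment sets: the fraction below 0.05 ("near-zero
mass") is the positivity signal, and an increase of at least five
percentage points raises a flag. The sensitivity analysis re-runs all
estimators with the seven process-of-care indicators added to the
adjustment set and reports per-clinic and pooled deltas. In the synthetic
cohort the indicators are consequences of exposure with no outcome role —
instrument-like — so the expected pattern, asserted by the acceptance
computation, is a sharply inflated near-zero mass with a pooled estimate
change within Monte-Carlo error.

## Numerical choices

Probability clips at 1e-6 (predictions) and [0.01, 0.99]
(potential-outcome construction); intercept and treatment-coefficient
calibration by `uniroot` to 1e-10/1e-12 on the realized sample; Newton
polishing of the fluctuation score to 1e-13; propensity truncation at
[0.025, 0.975]; continuous tree splits at rpart's adjacent-value
midpoints with deterministic tie-breaking, making trees invariant to row
order; fold assignment, bootstrap and replicate seeds all derived from one
integer so every artifact is bitwise reproducible.

Problem sizes used by the shipped checks — e.g. 20,000 analysis records
for parameter recovery, 200 × 2,000 for the simulation, 50,000 for the
missingness contract, 50 replicates for the ensemble-oracle property —
were chosen as the package's own desk-scale defaults; all are plain
function arguments.

## Known limitations

Complete-case analysis is unbiased under MAR but inefficient at 62%
missingness, and MAR itself is untestable. The pooled CI accounts for
patient-level clustering but conditions on clinic effects rather than
modeling clinics as random. The g-computation bootstrap refits only the
outcome model (not the analysis-set construction). Blip trees carry no
inference on leaf means — no honest splitting or CATE-specific learners —
and, as above, subgroup discovery is power-limited at moderate n. The
generator's simplifications (no drop-out, shared covariate law, MAR only)
bound what the test suite can certify about real data.
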