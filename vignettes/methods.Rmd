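---
title: "Methods: emulating a new-user anticoagulant trial from claims-like data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a new-user anticoagulant trial from claims-like data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimstte)
```

## The design being emulated

`claimstte` implements the analysis a hypothetical randomized trial of
two oral-anticoagulant strategies would license, carried out on
observational claims-like data. The protocol components and their
observational analogs are:

* **Eligibility** at an index diagnosis (new-onset atrial fibrillation in
  a patient with a cancer record): age 66+, continuous enrollment,
  moderate-to-high stroke risk (CHA₂DS₂-VASc ≥ 2), an anticoagulant
  washout over the baseline year, no recent stroke (14 days) or bleeding/
  surgery (30 days), no end-stage renal disease, and no prior event of
  the analyzed outcome.
* **Assignment** by the first qualifying prescription fill within a
  grace period (default 3 months; 6 in sensitivity analyses). Follow-up
  starts at that fill — time zero, eligibility, and assignment coincide,
  which removes immortal-time and prevalent-user bias by construction.
* **Follow-up** to the earliest of the outcome, death, loss to follow-up,
  or administrative censoring at 12 months (36 in sensitivity analyses).
  Death censors rather than competes: the estimand is the hazard among
  those alive and under observation, matching the emulated protocol.
* **Causal contrasts**: the intention-to-treat analog (effect of
  initiating, ignoring later deviation) and the per-protocol analog
  (effect of sustaining treatment), the latter obtained by artificially
  censoring at deviation — a refill gap of 30+ days from the end of
  days' supply, or any fill of the other drug class — and reweighting
  for the selection that censoring induces.

## Estimation

**Weights.** Confounding is adjusted by stabilized
inverse-probability-of-treatment weights from a main-effects propensity
logit: arm A patients receive $P(A)/\hat p_i$, arm B patients
$P(B)/(1-\hat p_i)$. Selection by censoring is adjusted by stabilized
inverse-probability-of-censoring weights: for each censoring cause the
month-$k$ factor is
$\prod_{j \le k} [1-\hat p^{num}(j)]/[1-\hat p^{den}(j)]$, where the
denominator model conditions on the month index, baseline covariates,
and monthly time-varying covariates, and the stabilizing numerator model
omits the time-varying covariates. Both models are fit stratified by
treatment arm — the full-interaction form — because censoring hazards
and their covariate associations may differ between drug classes, and
arm is retained in the outcome model so stratified stabilization remains
valid. Per-protocol analyses multiply in a second, deviation-cause
factor. Total weights are truncated at the empirical 99th percentile
(95th in sensitivity analyses), computed by linear interpolation over
all person-months of the analysis at hand.

**Outcome model.** The weighted pooled logistic regression of the
monthly event indicator on arm, a month function, and covariates is the
standard marginal-structural-model estimator: an independence working
model with patient-clustered sandwich covariance (the robust variance is
what makes the person-month replication within patients legitimate).
With monthly hazards of order $10^{-3}$–$10^{-2}$, the exponentiated arm
coefficient tracks the continuous-time hazard ratio; the package's tests
require agreement with a Cox partial-likelihood fit within 2% on such
data. Intention-to-treat models adjust for baseline covariates only;
per-protocol models add the time-varying covariates.

**Risk curves and risk differences.** Standardized (g-formula)
cumulative incidence per arm is obtained by predicting every patient's
monthly hazard with arm set to each value, converting to
$1-\prod(1-\hat h)$, and averaging with stabilized baseline weights. The
horizon risk difference is reported in percentage points; its interval,
when requested, comes from a nonparametric bootstrap over patients in
which weights and model are refit per replicate, so the interval
reflects the whole pipeline. Incidence rates use 30-day months and
365.25-day years.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `grace_period_months` | 3 | window after index in which the first fill assigns the arm |
| `gap_days` | 30 | refill gap defining discontinuation |
| `deviation_at` | `coverage_end` | deviation dated at the first uncovered day (`gap_complete` dates it after the full gap) |
| `horizon_months` | 12 | administrative censoring |
| `score_threshold` | 2 | CHA₂DS₂-VASc eligibility cut (NA = all levels) |
| `truncation` | 99 | weight-truncation percentile (`none`, 95, 99) |
| `n_imputations` | 1 | completed datasets; log-HRs pooled by Rubin's rules when > 1 |
| `time_form` | indicator ≤ 12 months, spline at 36 | month function in hazard models |

Where the emulated protocol was silent, the package makes the choice
explicit and configurable rather than implicit: months are fixed 30-day
half-open bins from treatment start (this makes the 30-day gap rule and
the 360-day horizon exact in integer day arithmetic); same-day first
fills of both classes are rejected as ambiguous unless a flag tie-breaks
them to the comparator arm; the outcome-free exclusion is applied per
analyzed outcome (a prior gastrointestinal bleed removes the patient
from the gastrointestinal-bleed analysis only), with a switch for the
global reading; overlapping same-class fills stockpile (supply carries
forward); and subgroup analyses refit weights within each stratum.

## The synthetic cohort generator

Because the motivating study's data are restricted-access, the generator
is a first-class module: it emulates the *structure* of such a cohort —
a two-arm point exposure initiated within a grace period, baseline
confounders that jointly drive treatment choice and outcome, monthly
binary time-varying covariates (two-state Markov chains) that drive
deviation and loss to follow-up, rare monthly event odds, death, and
administrative end of follow-up — with every pathway behind an explicit
log-odds knob. Per-patient RNG substreams are split from the root seed,
so identical configurations are byte-identical and growing the cohort
appends patients without reshuffling existing ones.

Two generator choices deserve note. First, loss to follow-up takes
effect at the end of its month: enrollment-based censoring is a
month-resolution event, and dating it mid-month would mask same-month
outcome events in a way no censoring weight can restore. Second, the
time-varying covariates expose arm-interaction knobs (`lo_onset_armA`,
`lo_ltfu_armA`): a covariate-dependent dropout that is *identical* in
both arms tilts both risk sets equally and leaves the marginal hazard
ratio essentially unbiased, so constructing genuinely informative
censoring requires censoring selection that differs by arm. Defaults
keep both knobs at zero.

Ground truth comes from `compute_true_marginal_hr()`: the configuration
is re-run with treatment randomized 1:1, deviation and censoring
switched off, and the marginal hazard ratio estimated as the
Mantel–Haenszel common odds ratio across month strata — a closed-form
tabulation sharing no code with the pipeline's estimation path.

What the generator does **not** emulate: diagnosis/procedure coding and
its measurement error, within-class drug heterogeneity, seasonal or
calendar structure, correlated comorbidity clusters, continuous
covariates in the confounder set, and dependence between death and the
outcome process. Passing recovery tests therefore demonstrates that the
estimators remove the biases they target under a correctly specified
generating process — not that any real-data analysis is unconfounded.

## Validation scenarios and problem sizes

The shipped scenarios (`sim_scenario_*()`) isolate one threat each; the
test suite and `scripts/acceptance.R` run them at these sizes, chosen to
keep Monte-Carlo error a small fraction of each assertion band:

* *Null calibration*: 200 replicates of n = 2,000 with true HR 1;
  the cluster-robust 95% CI must cover 1 in 90–98% of replicates.
* *Confounding removal*: one n = 50,000 cohort with a single strong
  confounder (prevalence 0.5, log-odds +1.5 on treatment, +1.0 on
  outcome) and conditional HR 0.7; the unadjusted estimator must be
  biased by more than 10% while the IPTW-weighted estimator lands within
  5% of the randomized-oracle truth (oracle n = 200,000).
* *Informative loss to follow-up*: n = 50,000 with a persistent flag
  raising the outcome odds ~3-fold and dropout in the comparator arm
  only; the unweighted estimator must fall outside 7% of truth and the
  IPCW-weighted one within 7%.
* *Per-protocol machinery*: n = 50,000 with arm-specific
  discontinuation rates and a flag driving both deviation and outcome;
  deviation-cause IPCW must cut the absolute log-HR bias by at least
  half.

## Numerical choices and degenerate inputs

* Propensity and censoring logits use tight IRLS convergence
  (`epsilon = 1e-14`); the stabilization identity (weighted arm share =
  unweighted share) is exact only at the score root and only for
  saturated models, and is tested in that form.
* Complete separation in the treatment or outcome model is an error
  naming the offending covariate; fitted probabilities of 0/1 in any
  weight denominator are positivity violations and fail loudly. An
  opt-in probability floor is deliberately absent: silent clipping hides
  exactly the pathology the diagnostics exist to surface.
* A censoring cause with zero events degenerates to hazard 0 and weights
  of 1, with a warning.
* Zero events in an arm flags the estimate (`hr = NA`, CI `(0, ∞)`)
  instead of crashing; subgroup strata inherit this behavior.
* Terminal-day ties resolve event > death > loss to follow-up >
  deviation > administrative.
* The outcome-model separation check inspects only covariate
  coefficients: month indicators may legitimately diverge in sparse
  months of small fixtures.
* Imputation: chained equations run a fixed five sweeps; binary
  variables use posterior-draw logistic imputation, factors multinomial
  draws, continuous variables type-1 predictive mean matching with five
  donors (every imputed value is an observed value). Constant predictors
  are dropped from imputation models.

## Known limitations

* No competing-risk estimators (death is censoring, per the emulated
  protocol); no doubly-robust (TMLE/AIPW) estimation; no overlap or
  matching weights.
* The bootstrap risk-difference interval refits weights and model per
  replicate and is correspondingly slow; it is off by default
  (`bootstrap_reps = 0`), in which case the adjusted risk difference is
  reported as a point estimate only.
* Multinomial imputation draws from fitted class probabilities without a
  parameter draw, slightly understating between-imputation variance for
  factor covariates.
* Tables are read and written as CSV; the generator and pipeline treat
  columns by name, so other tabular formats can be converted upstream.
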