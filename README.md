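# claimstte

Target-trial emulation for two-arm new-user cohorts built from
longitudinal claims-like data, with oral-anticoagulant initiation in
elderly atrial-fibrillation/cancer patients as the motivating design.

Observational comparisons of a preferred drug class (arm A, e.g. direct
oral anticoagulants) against a comparator (arm B, e.g. warfarin) are
prone to confounding by indication, immortal-time bias, and informative
loss to follow-up. `claimstte` implements the full emulation pipeline a
biostatistician would specify for such a study, plus a synthetic
claims-cohort generator with known ground truth so every stage can be
validated by parameter recovery:

1. **Cohort construction** — sequential eligibility criteria with an
   attrition report (minimum age, enrollment, CHA₂DS₂-VASc ≥ 2 stroke
   risk, anticoagulant washout, contraindications, outcome-free at
   baseline), arm assignment by the first qualifying fill inside a grace
   period (default 3 months), and time zero aligned at treatment start.
2. **Person-time** — expansion into 30-day person-months (month *k*
   covers days \[30k, 30(k+1)) from treatment start), follow-up ending at
   the outcome, death, loss to follow-up, or the 12-month administrative
   horizon; per-protocol analyses additionally censor at treatment
   deviation (a ≥ 30-day refill gap or a switch of drug class).
3. **Weighting** — stabilized inverse-probability-of-treatment weights
   from a propensity logit, times cumulative stabilized
   inverse-probability-of-censoring weights from arm-stratified pooled
   logits of each censoring cause, truncated at the 99th percentile.
4. **Estimation** — the marginal structural discrete-time hazard model:
   a weighted pooled logistic regression of the monthly event indicator
   on arm and a month function, with patient-clustered sandwich variance.
   For rare monthly events, exp(arm coefficient) approximates the hazard
   ratio of a continuous-time model. Standardized (g-formula) cumulative
   incidence curves and horizon risk differences follow from the fitted
   hazards.

The monthly event model is
`logit P(Y_t = 1 | T, L) = α_t + β·1{arm A} + γ'L`, the stabilized
treatment weight is `P(A)/p̂ᵢ` for arm A and `P(B)/(1−p̂ᵢ)` for arm B, and
the month-*k* censoring weight is
`Π_{j≤k} [1 − p̂ⁿᵘᵐ(j)] / [1 − p̂ᵈᵉⁿ(j)]` per censoring cause.

Scores: `cha2ds2_vasc()` and `has_bled()` compute the standard additive
stroke- and bleeding-risk scores from component flags. Missing baseline
covariates are completed by chained equations (`impute_missing()`:
logistic draws for binary, multinomial for factors, predictive mean
matching for continuous variables).

## Worked example

```r
library(claimstte)

cfg <- sim_config(n_patients = 4000, seed = 7)   # synthetic claims cohort
co  <- generate_cohort(cfg)                      # baseline, fills, events, tv

ac  <- analysis_config(
  estimands = c("ITT", "PP"), outcomes = "primary",
  covariate_names    = c("frail", "advanced_disease"),
  tv_covariate_names = c("thrombocytopenia_t", "akd_t"))
res <- run_analysis(ac, co)

print_attrition(res$attrition$primary)
render_estimates(res$estimates)
```

The attrition report chains every eligibility criterion down to the
analyzed cohort (here 4,000 simulated patients reduce to 3,164):

```
criterion                                   before  excluded     after
age >= minimum                                4000         0      4000
prior cancer record                           4000         0      4000
continuous enrollment                         4000       105      3895
stroke-risk score threshold                   3895       167      3728
anticoagulant washout                         3728       212      3516
no contraindication                           3516       152      3364
no stroke within 14 days                      3364        37      3327
no recent bleeding/surgery                    3327        69      3258
no end-stage renal disease                    3258        56      3202
outcome-free before treatment start           3202        38      3164
```

and the rendered estimates give, per estimand, event counts, incidence
rates per 1,000 person-years, and unadjusted/adjusted contrasts (the
generator's true hazard ratio here is 1):

```
  estimand outcome events_A events_B  ir_A  ir_B            unadj_rd
1      ITT primary       91       55 47.91 60.23 -1.15 (-2.78, 0.48)
2       PP primary       83       37 50.41 53.50  0.24 (-1.16, 1.65)
           unadj_hr            adj_hr
1 0.79 (0.57, 1.11) 0.99 (0.70, 1.41)
2 0.94 (0.64, 1.39) 1.12 (0.74, 1.68)
```

The adjusted intention-to-treat hazard ratio is 0.99 (0.70–1.41): after
inverse-probability weighting, the confounded unadjusted contrast (0.79)
moves back to the null, and the post-weighting standardized mean
differences of both confounders are below 0.001. Counts below 11 are
rendered as "–" when suppression is on; stored tables are never masked.

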