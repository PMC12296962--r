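#' Specify baseline confounders for the synthetic cohort
#'
#' Each confounder is a binary baseline covariate with a prevalence, a
#' log-odds effect on choosing arm A over arm B, and a log-odds effect on
#' the monthly outcome odds. Nonzero values on both pathways create
#' classical confounding that the weighting stage must remove.
#'
#' @param name Covariate names.
#' @param prevalence Marginal prevalence in `[0, 1]`.
#' @param lo_treat Log-odds effect on treatment (arm A) choice.
#' @param lo_outcome Log-odds effect on the monthly event odds.
#' @return A data.frame with one row per confounder.
#' @export
confounder_spec <- function(name, prevalence, lo_treat = 0, lo_outcome = 0) {
  check_prob(prevalence, "prevalence")
  out <- data.frame(name = as.character(name),
                    prevalence = as.numeric(prevalence),
                    lo_treat = as.numeric(lo_treat),
                    lo_outcome = as.numeric(lo_outcome),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$name)) tte_stop("duplicate confounder names")
  out
}

#' Specify binary time-varying covariates for the synthetic cohort
#'
#' Each covariate follows a two-state Markov chain over follow-up months
#' (transition probabilities `p01` off-to-on and `p10` on-to-off) and can
#' shift, on the log-odds scale, the monthly hazards of treatment deviation
#' (discontinuation), loss to follow-up, and the outcome itself. Nonzero
#' `lo_ltfu`/`lo_deviation` together with nonzero `lo_outcome` make
#' censoring informative, the situation inverse-probability-of-censoring
#' weights exist to fix.
#'
#' @param name Covariate names.
#' @param init_prev Month-0 prevalence.
#' @param p01,p10 Monthly transition probabilities.
#' @param lo_deviation,lo_ltfu,lo_outcome Log-odds effects on the monthly
#'   deviation, loss-to-follow-up, and outcome hazards.
#' @param lo_onset_armA Log-odds shift of the off-to-on transition for arm
#'   A patients, making the covariate's dynamics treatment-dependent (a
#'   treatment-affected intermediate, e.g. a drug-induced condition).
#' @param lo_ltfu_armA Additional log-odds effect of the covariate on loss
#'   to follow-up in arm A only (an arm-by-covariate interaction; censoring
#'   selection that differs between arms is what makes loss to follow-up
#'   bias the marginal hazard ratio).
#' @return A data.frame with one row per covariate.
#' @export
tv_covariate_spec <- function(name, init_prev, p01, p10,
                              lo_deviation = 0, lo_ltfu = 0, lo_outcome = 0,
                              lo_onset_armA = 0, lo_ltfu_armA = 0) {
  check_prob(init_prev, "init_prev"); check_prob(p01, "p01"); check_prob(p10, "p10")
  out <- data.frame(name = as.character(name),
                    init_prev = as.numeric(init_prev),
                    p01 = as.numeric(p01), p10 = as.numeric(p10),
                    lo_deviation = as.numeric(lo_deviation),
                    lo_ltfu = as.numeric(lo_ltfu),
                    lo_outcome = as.numeric(lo_outcome),
                    lo_onset_armA = as.numeric(lo_onset_armA),
                    lo_ltfu_armA = as.numeric(lo_ltfu_armA),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$name)) tte_stop("duplicate time-varying covariate names")
  out
}

#' Configuration for the synthetic claims-cohort generator
#'
#' Defines a two-arm point-exposure cohort: an index diagnosis at day 0,
#' initiation of one of two drug classes within a grace period, 30-day
#' prescription fills with stochastic discontinuation and switching,
#' monthly binary time-varying covariates, rare monthly outcome events,
#' death, loss to follow-up, and administrative end of follow-up. Time is
#' discretized to 30-day months; month k covers days `[30k, 30(k+1))` from
#' treatment start.
#'
#' Defaults emulate an elderly anticoagulant-initiator cohort with cancer:
#' 7,000 patients, roughly 3:1 split toward the DOAC-like arm A, monthly
#' event odds of 3e-3, 12-month administrative horizon, 3-month grace
#' period, and moderate baseline confounding.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Root seed; per-patient streams are split from it so changing
#'   `n_patients` never reshuffles earlier patients.
#' @param true_log_hr Conditional log hazard ratio of arm A vs arm B on the
#'   monthly event odds (applies to every outcome unless `outcomes` is given).
#' @param baseline_event_odds Monthly event odds in (0, 1) at covariate zero.
#' @param outcomes Optional data.frame (name, baseline_event_odds,
#'   true_log_hr) defining several independent outcome streams; defaults to
#'   a single stream called `"primary"` built from the scalar arguments.
#' @param confounders See [confounder_spec()].
#' @param tv_covariates See [tv_covariate_spec()].
#' @param treatment_intercept Log-odds of arm A at covariate zero.
#' @param monthly_discontinuation_prob Named per-arm monthly probabilities
#'   `c(A = , B = )` of stopping refills.
#' @param monthly_switch_prob Named per-arm monthly probabilities of
#'   switching to the other drug class.
#' @param monthly_ltfu_prob Monthly loss-to-follow-up probability at
#'   time-varying covariate zero.
#' @param monthly_death_prob Monthly death probability.
#' @param grace_period_months Grace period (months) for first fill.
#' @param admin_horizon_months Administrative follow-up horizon in months.
#' @param missingness_prob Named vector of per-covariate
#'   missing-completely-at-random probabilities (at most 8 covariates).
#' @param pre_treatment_event_prob Probability that a patient carries an
#'   outcome event dated between index and treatment start (such patients
#'   are what the outcome-free eligibility criterion exists to exclude).
#' @param exclusion_flag_prevalence Named prevalences for the baseline
#'   exclusion flags (`prior_oac`, `contraindication`, `recent_stroke_14d`,
#'   `recent_bleed_30d`, `renal_failure`, `non_continuous_enrollment`,
#'   `thrombocytopenia`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 7000L,
                       seed = 20260101L,
                       true_log_hr = 0,
                       baseline_event_odds = 0.003,
                       outcomes = NULL,
                       confounders = confounder_spec(
                         name = c("frail", "advanced_disease"),
                         prevalence = c(0.35, 0.20),
                         lo_treat = c(-0.8, -0.6),
                         lo_outcome = c(0.6, 0.5)),
                       tv_covariates = tv_covariate_spec(
                         name = c("thrombocytopenia_t", "akd_t"),
                         init_prev = c(0.05, 0.04),
                         p01 = c(0.02, 0.02), p10 = c(0.30, 0.40),
                         lo_deviation = c(0.4, 0.3),
                         lo_ltfu = c(0.3, 0.2),
                         lo_outcome = c(0.4, 0.3)),
                       treatment_intercept = qlogis(0.78),
                       monthly_discontinuation_prob = c(A = 0.03, B = 0.05),
                       monthly_switch_prob = c(A = 0.002, B = 0.008),
                       monthly_ltfu_prob = 0.005,
                       monthly_death_prob = 0.010,
                       grace_period_months = 3L,
                       admin_horizon_months = 12L,
                       missingness_prob = numeric(0),
                       pre_treatment_event_prob = 0.01,
                       exclusion_flag_prevalence = c(
                         prior_oac = 0.05, contraindication = 0.04,
                         recent_stroke_14d = 0.01, recent_bleed_30d = 0.02,
                         renal_failure = 0.02, non_continuous_enrollment = 0.03,
                         thrombocytopenia = 0.05)) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || is.na(n_patients) ||
      n_patients < 1) {
    tte_stop("'n_patients' must be a positive integer")
  }
  if (!is.numeric(baseline_event_odds) || any(baseline_event_odds <= 0) ||
      any(baseline_event_odds >= 1)) {
    tte_stop("'baseline_event_odds' must lie in (0, 1)")
  }
  for (nm in c("monthly_ltfu_prob", "monthly_death_prob",
               "pre_treatment_event_prob")) {
    check_prob(get(nm), nm)
  }
  check_prob(monthly_discontinuation_prob, "monthly_discontinuation_prob")
  check_prob(monthly_switch_prob, "monthly_switch_prob")
  if (!all(c("A", "B") %in% names(monthly_discontinuation_prob)) ||
      !all(c("A", "B") %in% names(monthly_switch_prob))) {
    tte_stop("per-arm probabilities must be named c(A = , B = )")
  }
  if (grace_period_months < 1) tte_stop("'grace_period_months' must be >= 1")
  if (grace_period_months > admin_horizon_months) {
    tte_stop("'grace_period_months' must not exceed 'admin_horizon_months'")
  }
  if (length(missingness_prob)) {
    check_prob(missingness_prob, "missingness_prob")
    if (is.null(names(missingness_prob)) || any(names(missingness_prob) == "")) {
      tte_stop("'missingness_prob' must be a named vector")
    }
    if (length(missingness_prob) > 8L) {
      tte_stop("'missingness_prob' supports at most 8 covariates")
    }
  }
  check_prob(exclusion_flag_prevalence, "exclusion_flag_prevalence")
  if (is.null(outcomes)) {
    outcomes <- data.frame(name = "primary",
                           baseline_event_odds = baseline_event_odds,
                           true_log_hr = true_log_hr,
                           stringsAsFactors = FALSE)
  } else {
    check_cols(outcomes, c("name", "baseline_event_odds", "true_log_hr"),
               "outcomes")
    if (any(outcomes$baseline_event_odds <= 0 | outcomes$baseline_event_odds >= 1)) {
      tte_stop("'baseline_event_odds' must lie in (0, 1)")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    true_log_hr = true_log_hr, baseline_event_odds = baseline_event_odds,
    outcomes = outcomes, confounders = confounders,
    tv_covariates = tv_covariates,
    treatment_intercept = treatment_intercept,
    monthly_discontinuation_prob = monthly_discontinuation_prob,
    monthly_switch_prob = monthly_switch_prob,
    monthly_ltfu_prob = monthly_ltfu_prob,
    monthly_death_prob = monthly_death_prob,
    grace_period_months = as.integer(grace_period_months),
    admin_horizon_months = as.integer(admin_horizon_months),
    missingness_prob = missingness_prob,
    pre_treatment_event_prob = pre_treatment_event_prob,
    exclusion_flag_prevalence = exclusion_flag_prevalence),
    class = "sim_config")
}

#' Round-trip a simulation config through YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path to write to / read from.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$outcomes <- as.list(as.data.frame(x$outcomes))
  x$confounders <- as.list(as.data.frame(x$confounders))
  x$tv_covariates <- as.list(as.data.frame(x$tv_covariates))
  x$monthly_discontinuation_prob <- as.list(x$monthly_discontinuation_prob)
  x$monthly_switch_prob <- as.list(x$monthly_switch_prob)
  x$missingness_prob <- as.list(x$missingness_prob)
  x$exclusion_flag_prevalence <- as.list(x$exclusion_flag_prevalence)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(
    n_patients = x$n_patients, seed = x$seed,
    true_log_hr = x$true_log_hr,
    baseline_event_odds = x$baseline_event_odds,
    outcomes = as.data.frame(x$outcomes, stringsAsFactors = FALSE),
    confounders = as.data.frame(x$confounders, stringsAsFactors = FALSE),
    tv_covariates = as.data.frame(x$tv_covariates, stringsAsFactors = FALSE),
    treatment_intercept = x$treatment_intercept,
    monthly_discontinuation_prob = unlist(x$monthly_discontinuation_prob),
    monthly_switch_prob = unlist(x$monthly_switch_prob),
    monthly_ltfu_prob = x$monthly_ltfu_prob,
    monthly_death_prob = x$monthly_death_prob,
    grace_period_months = x$grace_period_months,
    admin_horizon_months = x$admin_horizon_months,
    missingness_prob = if (length(x$missingness_prob)) unlist(x$missingness_prob) else numeric(0),
    pre_treatment_event_prob = x$pre_treatment_event_prob,
    exclusion_flag_prevalence = unlist(x$exclusion_flag_prevalence))
}
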