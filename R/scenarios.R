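#' Validation scenario configurations
#'
#' Ready-made [sim_config()] objects for the package's standard
#' parameter-recovery studies. Each isolates one threat to validity so a
#' single pipeline stage can be checked against ground truth:
#'
#' \describe{
#'   \item{`sim_scenario_null()`}{Randomized arms, true hazard ratio 1, no
#'     confounding: the calibration scenario for confidence-interval
#'     coverage.}
#'   \item{`sim_scenario_confounding()`}{One strong binary confounder
#'     (prevalence 0.5, log-odds 1.5 on treatment and 1.0 on outcome) with
#'     conditional hazard ratio 0.7: the IPTW recovery scenario.}
#'   \item{`sim_scenario_informative_ltfu()`}{Randomized arms, a
#'     persistent time-varying flag that triples the outcome odds and
#'     raises loss to follow-up in the comparator arm only (an
#'     arm-by-covariate censoring interaction): the IPCW recovery
#'     scenario.}
#'   \item{`sim_scenario_informative_deviation()`}{Randomized arms, a
#'     time-varying flag driving both treatment discontinuation and
#'     outcome, with arm-specific discontinuation rates: the per-protocol
#'     deviation-weighting scenario.}
#' }
#'
#' Exclusion flags, pre-treatment events, and missingness are switched
#' off so the scenarios measure estimation, not cohort filtering.
#'
#' @param n_patients,seed Cohort size and root seed.
#' @return A [sim_config()] object.
#' @name sim_scenarios
NULL

#' @rdname sim_scenarios
#' @export
sim_scenario_null <- function(n_patients = 2000L, seed = 1L) {
  sim_config(
    n_patients = n_patients, seed = seed, true_log_hr = 0,
    baseline_event_odds = 0.008,
    confounders = confounder_spec("noise", 0.3, 0, 0),
    tv_covariates = tv_covariate_spec("flag_t", 0.05, 0.02, 0.3),
    treatment_intercept = 0,
    monthly_discontinuation_prob = c(A = 0, B = 0),
    monthly_switch_prob = c(A = 0, B = 0),
    monthly_ltfu_prob = 0.005, monthly_death_prob = 0.01,
    pre_treatment_event_prob = 0,
    exclusion_flag_prevalence = c(prior_oac = 0))
}

#' @rdname sim_scenarios
#' @export
sim_scenario_confounding <- function(n_patients = 50000L, seed = 11L) {
  sim_config(
    n_patients = n_patients, seed = seed, true_log_hr = log(0.7),
    baseline_event_odds = 0.005,
    confounders = confounder_spec("sev", 0.5, lo_treat = 1.5,
                                  lo_outcome = 1.0),
    tv_covariates = tv_covariate_spec("flag_t", 0.05, 0.02, 0.3),
    treatment_intercept = 0,
    monthly_discontinuation_prob = c(A = 0, B = 0),
    monthly_switch_prob = c(A = 0, B = 0),
    monthly_ltfu_prob = 0.004, monthly_death_prob = 0.008,
    pre_treatment_event_prob = 0,
    exclusion_flag_prevalence = c(prior_oac = 0))
}

#' @rdname sim_scenarios
#' @export
sim_scenario_informative_ltfu <- function(n_patients = 50000L, seed = 21L) {
  sim_config(
    n_patients = n_patients, seed = seed, true_log_hr = log(0.7),
    baseline_event_odds = 0.009,
    confounders = confounder_spec("noise", 0.3, 0, 0),
    tv_covariates = tv_covariate_spec(
      "flag_t", init_prev = 0.25, p01 = 0.03, p10 = 0.02,
      lo_ltfu = 1.8, lo_ltfu_armA = -1.8, lo_outcome = 1.2),
    treatment_intercept = 0,
    monthly_discontinuation_prob = c(A = 0, B = 0),
    monthly_switch_prob = c(A = 0, B = 0),
    monthly_ltfu_prob = 0.04, monthly_death_prob = 0.01,
    pre_treatment_event_prob = 0,
    exclusion_flag_prevalence = c(prior_oac = 0))
}

#' @rdname sim_scenarios
#' @export
sim_scenario_informative_deviation <- function(n_patients = 50000L,
                                               seed = 31L) {
  sim_config(
    n_patients = n_patients, seed = seed, true_log_hr = log(0.7),
    baseline_event_odds = 0.009,
    confounders = confounder_spec("noise", 0.3, 0, 0),
    tv_covariates = tv_covariate_spec(
      "flag_t", init_prev = 0.25, p01 = 0.03, p10 = 0.02,
      lo_deviation = 1.5, lo_outcome = 1.2),
    treatment_intercept = 0,
    monthly_discontinuation_prob = c(A = 0.02, B = 0.08),
    monthly_switch_prob = c(A = 0.002, B = 0.005),
    monthly_ltfu_prob = 0.005, monthly_death_prob = 0.01,
    pre_treatment_event_prob = 0,
    exclusion_flag_prevalence = c(prior_oac = 0))
}
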