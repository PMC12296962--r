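#' Ground-truth marginal hazard ratio by randomized mega-simulation
#'
#' Estimates the marginal (population-averaged) hazard ratio implied by a
#' simulation configuration, for use as the recovery target in validation
#' studies. The configuration is re-run with treatment randomized 1:1
#' (all confounder effects on treatment zeroed), no treatment deviation,
#' and no censoring other than the administrative horizon; the marginal HR
#' is then the Mantel-Haenszel common odds ratio of the monthly event
#' indicator across follow-up-month strata. Because monthly hazards are
#' small, the discrete-hazard odds ratio coincides with the hazard ratio
#' to first order.
#'
#' The estimator is a closed-form tabulation and shares no code with the
#' pipeline's pooled-logistic estimation path.
#'
#' @param config A [sim_config()]; only its outcome and confounder-outcome
#'   structure is used.
#' @param oracle_n Number of randomized patients (>= 2; 1e5+ recommended).
#' @param oracle_seed Seed for the oracle simulation.
#' @param outcome Outcome name; defaults to the first configured outcome.
#' @return A list of class `truth_record` with `true_log_hr`,
#'   `true_marginal_hr`, `oracle_n`, `oracle_seed`.
#' @export
compute_true_marginal_hr <- function(config, oracle_n = 1e5,
                                     oracle_seed = config$seed + 1L,
                                     outcome = NULL) {
  if (!inherits(config, "sim_config")) {
    tte_stop("'config' must be a sim_config object")
  }
  if (oracle_n < 2) tte_stop("'oracle_n' must be >= 2")
  outcome <- outcome %||% config$outcomes$name[[1L]]
  o <- match(outcome, config$outcomes$name)
  if (is.na(o)) tte_stop("unknown outcome '", outcome, "'")

  rand <- config
  rand$n_patients <- as.integer(oracle_n)
  rand$seed <- as.integer(oracle_seed %% 2147483647)
  rand$confounders$lo_treat <- 0
  rand$treatment_intercept <- 0
  rand$monthly_discontinuation_prob[] <- 0
  rand$monthly_switch_prob[] <- 0
  rand$monthly_ltfu_prob <- 0
  rand$monthly_death_prob <- 0
  rand$pre_treatment_event_prob <- 0
  rand$missingness_prob <- numeric(0)

  cohort <- generate_cohort(rand)
  H <- rand$admin_horizon_months

  first_fill <- cohort$fills[, list(start = min(day), arm = drug_class[1L]),
                             by = patient_id]
  ev <- cohort$events[type == outcome]
  ev <- merge(ev, first_fill, by = "patient_id")
  ev[, month := (day - start) %/% 30L]
  ev <- ev[month >= 0L & month < H]
  ev_month <- rep(NA_integer_, oracle_n)
  ev_month[ev$patient_id] <- ev$month
  armA <- first_fill$arm[order(first_fill$patient_id)] == "A"

  ## Mantel-Haenszel common odds ratio over month strata
  num <- 0; den <- 0
  for (m in seq_len(H) - 1L) {
    at_risk <- is.na(ev_month) | ev_month >= m
    a <- sum(armA & at_risk & !is.na(ev_month) & ev_month == m)
    c_ <- sum(!armA & at_risk & !is.na(ev_month) & ev_month == m)
    b <- sum(armA & at_risk) - a
    d <- sum(!armA & at_risk) - c_
    n_m <- a + b + c_ + d
    if (n_m > 0) {
      num <- num + a * d / n_m
      den <- den + b * c_ / n_m
    }
  }
  if (den == 0) tte_stop("no events in one arm; oracle HR undefined")
  structure(list(true_log_hr = config$outcomes$true_log_hr[[o]],
                 true_marginal_hr = num / den,
                 oracle_n = as.integer(oracle_n),
                 oracle_seed = as.integer(oracle_seed %% 2147483647)),
            class = "truth_record")
}
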