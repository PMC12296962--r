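## Fixed prevalences for the clinical-flavour baseline fields. These are
## descriptive dressing for an elderly anticoagulant/cancer cohort; the
## covariates that drive treatment and outcome are the configured
## confounders, so these constants never enter recovery properties.
.risk_component_prev <- c(
  chf = 0.20, hypertension = 0.70, diabetes = 0.25, stroke_tia_history = 0.06,
  vascular_disease = 0.20, renal_disease = 0.10, liver_disease = 0.04,
  bleeding_history = 0.08, labile_inr = 0.10, alcohol_use = 0.05,
  antiplatelet_or_nsaid = 0.25)

#' Generate a synthetic claims-like cohort
#'
#' Simulates the full longitudinal structure of a two-arm new-user cohort:
#' baseline covariates and exclusion flags, a first anticoagulant fill
#' inside the grace period, a chain of 30-day refills with stochastic
#' discontinuation and class switching, monthly binary time-varying
#' covariates (two-state Markov chains), independent rare outcome-event
#' streams, death, and loss to follow-up. All days are integers counted
#' from each patient's index diagnosis (day 0); the first fill day is the
#' patient's treatment start.
#'
#' Each patient draws from an RNG substream split deterministically from
#' the root seed, so the same `(config, seed)` always produces
#' byte-identical tables and increasing `n_patients` appends patients
#' without reshuffling existing ones.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `tte_cohort` with elements `baseline` (one row
#'   per patient), `fills` (dated drug fills with days' supply), `events`
#'   (at most one row per outcome type per patient, plus at most one
#'   death/ltfu row), and `tv` (patient x follow-up-month time-varying
#'   covariates), all `data.table`s.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    tte_stop("'config' must be a sim_config object")
  }
  n <- config$n_patients
  H <- config$admin_horizon_months
  conf <- config$confounders
  tvs <- config$tv_covariates
  outs <- config$outcomes
  nc <- nrow(conf); ntv <- nrow(tvs); nout <- nrow(outs)

  ## ---- per-patient uniform budget ------------------------------------
  ## baseline block: age, sex, 11 risk components, 5 cancer fields,
  ## 7 exclusion flags, nc confounders, arm, first-fill day,
  ## 3 pre-treatment-event draws, 8 missingness slots
  n_base <- 2L + 11L + 5L + 7L + nc + 2L + 3L + 8L
  ## monthly block per month: ntv transitions, nout event draws,
  ## death, ltfu, discontinuation, switch
  n_month <- ntv + nout + 4L
  ## trailing offsets: event day offset per outcome, death, ltfu
  B <- n_base + H * n_month + nout + 2L

  umat <- matrix(0, nrow = n, ncol = B)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    umat[i, ] <- runif(B)
  }
  ptr <- 0L
  u <- function(k = 1L) {
    cols <- ptr + seq_len(k); ptr <<- ptr + k
    umat[, cols, drop = (k == 1L)]
  }

  ## ---- baseline ------------------------------------------------------
  age <- 66 + pmin(floor(-8 * log(u())), 32)
  sex <- ifelse(u() < 0.5, "female", "male")
  comp <- matrix(FALSE, nrow = n, ncol = length(.risk_component_prev),
                 dimnames = list(NULL, names(.risk_component_prev)))
  for (nm in colnames(comp)) comp[, nm] <- u() < .risk_component_prev[[nm]]
  cancer_type <- c("breast", "lung", "prostate")[
    findInterval(u(), c(0, 0.35, 0.65)) ]
  cancer_status <- ifelse(u() < 0.40, "active", "history")
  cancer_stage <- c("local", "regional", "distant")[
    findInterval(u(), c(0, 0.55, 0.85)) ]
  tumor_grade <- c("I", "II", "III")[findInterval(u(), c(0, 0.25, 0.70))]
  months_since_cancer_dx <- round(u() * 120, 1)

  efp <- config$exclusion_flag_prevalence
  flag_names <- c("prior_oac", "contraindication", "recent_stroke_14d",
                  "recent_bleed_30d", "renal_failure",
                  "non_continuous_enrollment", "thrombocytopenia")
  flags <- matrix(FALSE, nrow = n, ncol = length(flag_names),
                  dimnames = list(NULL, flag_names))
  for (nm in flag_names) {
    p_flag <- if (nm %in% names(efp)) efp[[nm]] else 0
    flags[, nm] <- u() < p_flag
  }

  X <- matrix(0, nrow = n, ncol = nc,
              dimnames = list(NULL, conf$name))
  for (j in seq_len(nc)) X[, j] <- as.numeric(u() < conf$prevalence[j])

  p_arm <- plogis(config$treatment_intercept +
                    drop(X %*% conf$lo_treat))
  latent_arm <- ifelse(u() < p_arm, "A", "B")
  first_fill_day <- floor(u() * 30 * config$grace_period_months)

  u_pre <- u(); u_pre_which <- u(); u_pre_day <- u()
  u_miss <- u(8L)

  ## ---- monthly processes ---------------------------------------------
  z <- matrix(0, nrow = n, ncol = ntv, dimnames = list(NULL, tvs$name))
  tv_paths <- array(0, dim = c(n, H, ntv))
  event_month <- matrix(NA_integer_, nrow = n, ncol = nout)
  death_month <- rep(NA_integer_, n)
  ltfu_month <- rep(NA_integer_, n)
  disc_month <- rep(NA_integer_, n)
  switch_month <- rep(NA_integer_, n)

  armA <- as.numeric(latent_arm == "A")
  disc_base <- qlogis(unname(config$monthly_discontinuation_prob[latent_arm]))
  switch_base <- qlogis(unname(config$monthly_switch_prob[latent_arm]))
  ltfu_base <- qlogis(config$monthly_ltfu_prob)
  conf_out_eff <- drop(X %*% conf$lo_outcome)

  for (m in seq_len(H) - 1L) {
    for (j in seq_len(ntv)) {
      uj <- u()
      p01j <- plogis(qlogis(tvs$p01[j]) + armA * tvs$lo_onset_armA[j])
      if (m == 0L) {
        z[, j] <- as.numeric(uj < tvs$init_prev[j])
      } else {
        z[, j] <- ifelse(z[, j] == 1,
                         as.numeric(uj >= tvs$p10[j]),
                         as.numeric(uj < p01j))
      }
      tv_paths[, m + 1L, j] <- z[, j]
    }
    tv_out_eff <- drop(z %*% tvs$lo_outcome)
    tv_dev_eff <- drop(z %*% tvs$lo_deviation)
    tv_ltfu_eff <- drop(z %*% tvs$lo_ltfu) +
      armA * drop(z %*% tvs$lo_ltfu_armA)

    for (o in seq_len(nout)) {
      p_ev <- plogis(log(outs$baseline_event_odds[o]) + conf_out_eff +
                       tv_out_eff + armA * outs$true_log_hr[o])
      hit <- (u() < p_ev) & is.na(event_month[, o])
      event_month[hit, o] <- m
    }
    hit <- (u() < config$monthly_death_prob) & is.na(death_month)
    death_month[hit] <- m
    hit <- (u() < plogis(ltfu_base + tv_ltfu_eff)) & is.na(ltfu_month)
    ltfu_month[hit] <- m
    u_disc <- u(); u_switch <- u()
    if (m >= 1L) {
      hit <- (u_disc < plogis(disc_base + tv_dev_eff)) & is.na(disc_month)
      disc_month[hit] <- m
      hit <- (u_switch < plogis(switch_base)) & is.na(switch_month)
      switch_month[hit] <- m
    }
  }
  u_ev_off <- matrix(u(nout), nrow = n)
  u_death_off <- u(); u_ltfu_off <- u()

  ## ---- assemble tables -----------------------------------------------
  baseline <- data.table::data.table(
    patient_id = seq_len(n), index_day = 0L,
    age_at_index = as.numeric(age), sex = sex)
  for (nm in colnames(comp)) baseline[[nm]] <- comp[, nm]
  baseline$uncontrolled_htn <- baseline$hypertension & (umat[, 1L] < 0.5)
  baseline$cancer_type <- cancer_type
  baseline$cancer_status <- cancer_status
  baseline$cancer_stage <- cancer_stage
  baseline$tumor_grade <- tumor_grade
  baseline$months_since_cancer_dx <- months_since_cancer_dx
  for (nm in flag_names) baseline[[nm]] <- flags[, nm]
  baseline$continuous_enrollment <- !baseline$non_continuous_enrollment
  baseline$non_continuous_enrollment <- NULL
  for (j in seq_len(nc)) baseline[[conf$name[j]]] <- X[, j]
  baseline$cha2ds2_vasc <- cha2ds2_vasc(
    baseline$age_at_index, baseline$sex, baseline$chf, baseline$hypertension,
    baseline$diabetes, baseline$stroke_tia_history, baseline$vascular_disease)
  baseline$has_bled <- has_bled(
    baseline$age_at_index, baseline$uncontrolled_htn, baseline$renal_disease,
    baseline$liver_disease, baseline$stroke_tia_history,
    baseline$bleeding_history, baseline$labile_inr,
    baseline$antiplatelet_or_nsaid, baseline$alcohol_use)
  baseline$arm <- NA_character_
  baseline$treatment_start_day <- NA_integer_

  ## fills: assigned-class chain from the first fill until deviation,
  ## death, loss to follow-up, or the horizon; switchers then continue in
  ## the other class.
  start <- as.integer(first_fill_day)
  censor_m <- pmin(death_month, ltfu_month, na.rm = TRUE)
  censor_m[is.na(censor_m)] <- H
  stop_m <- pmin(disc_month, switch_month, censor_m, H, na.rm = TRUE)
  stop_m <- pmax(stop_m, 1L)  # the qualifying first fill always exists

  fills <- data.table::data.table(
    patient_id = rep(seq_len(n), stop_m),
    fill_no = sequence(stop_m))
  fills[, day := start[patient_id] + 30L * (fill_no - 1L)]
  fills[, drug_class := latent_arm[patient_id]]
  fills[, days_supply := 30L]
  fills[, fill_no := NULL]

  switched <- !is.na(switch_month) & switch_month == stop_m &
    switch_month < censor_m &
    (is.na(disc_month) | switch_month <= disc_month)
  if (any(switched)) {
    ids <- which(switched)
    n_sw <- censor_m[ids] - switch_month[ids]
    sw <- data.table::data.table(
      patient_id = rep(ids, n_sw), fill_no = sequence(n_sw))
    sw[, day := start[patient_id] + 30L *
         (switch_month[patient_id] + fill_no - 1L)]
    sw[, drug_class := ifelse(latent_arm[patient_id] == "A", "B", "A")]
    sw[, days_supply := 30L]
    sw[, fill_no := NULL]
    fills <- rbind(fills, sw)
  }
  ## baseline-period fills for patients flagged with prior anticoagulant
  ## use (these are what the washout criterion removes)
  prior <- which(baseline$prior_oac)
  if (length(prior)) {
    pre <- data.table::data.table(
      patient_id = prior,
      day = -30L - (prior %% 300L),
      drug_class = latent_arm[prior], days_supply = 30L)
    fills <- rbind(fills, pre)
  }
  data.table::setkey(fills, patient_id, day)

  ## events: one latent first-event record per outcome type
  ev_list <- vector("list", nout + 1L)
  for (o in seq_len(nout)) {
    has <- !is.na(event_month[, o])
    ev_day <- start + 30L * event_month[, o] + floor(u_ev_off[, o] * 30)
    ## a pre-treatment event supersedes the post-treatment stream
    pre_hit <- (u_pre < config$pre_treatment_event_prob) &
      (floor(u_pre_which * nout) + 1L == o) & (start > 0L)
    ev_day[pre_hit] <- floor(u_pre_day[pre_hit] * start[pre_hit])
    has <- has | pre_hit
    ev_list[[o]] <- data.table::data.table(
      patient_id = which(has), type = outs$name[o],
      day = as.integer(ev_day[has]))
  }
  death_day <- start + 30L * death_month + floor(u_death_off * 30)
  ## enrollment-based loss to follow-up takes effect at the end of its
  ## month, so outcome events earlier in the same month remain observable
  ltfu_day <- start + 30L * ltfu_month + 29L
  take_death <- !is.na(death_month) &
    (is.na(ltfu_month) | death_month <= ltfu_month)
  take_ltfu <- !is.na(ltfu_month) & !take_death
  ev_list[[nout + 1L]] <- rbind(
    data.table::data.table(patient_id = which(take_death), type = "death",
                           day = as.integer(death_day[take_death])),
    data.table::data.table(patient_id = which(take_ltfu), type = "ltfu",
                           day = as.integer(ltfu_day[take_ltfu])))
  events <- data.table::rbindlist(ev_list)
  data.table::setkey(events, patient_id, day)

  ## tv table: follow-up months 0..H-1 (months count from treatment start)
  tv <- data.table::data.table(
    patient_id = rep(seq_len(n), each = H),
    month = rep(seq_len(H) - 1L, times = n))
  for (j in seq_len(ntv)) {
    tv[[tvs$name[j]]] <- as.numeric(t(tv_paths[, , j]))
  }

  ## missing-at-random covariate values
  mp <- config$missingness_prob
  if (length(mp)) {
    for (j in seq_along(mp)) {
      nm <- names(mp)[j]
      if (!nm %in% names(baseline)) {
        tte_stop("missingness_prob names unknown covariate '", nm, "'")
      }
      baseline[[nm]][u_miss[, j] < mp[j]] <- NA
    }
  }

  structure(list(baseline = baseline, fills = fills, events = events,
                 tv = tv),
            class = "tte_cohort")
}
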