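#' Incidence rate per 1000 person-years
#'
#' Person-months are converted to years with 30-day months and
#' 365.25-day years.
#'
#' @param n_events Event count.
#' @param person_months Person-months at risk (> 0).
#' @return Events per 1000 person-years.
#' @examples
#' incidence_rate(10, 121.75 * 365.25 / 30)  # 82.14 per 1000 py
#' @export
incidence_rate <- function(n_events, person_months) {
  if (any(person_months <= 0)) tte_stop("'person_months' must be positive")
  1000 * n_events / (person_months * 30 / 365.25)
}

#' Unadjusted risk difference with a Wald confidence interval
#'
#' Closed-form contrast of two binomial proportions:
#' `rd = 100 (e1/n1 - e0/n0)` percentage points with the usual Wald 95%
#' interval. This is the "unadjusted RD" a two-arm cohort table reports
#' from raw event counts.
#'
#' @param e1,n1 Events and patients, exposed arm.
#' @param e0,n0 Events and patients, reference arm.
#' @param level Confidence level.
#' @return List `rd`, `ci` (percentage points, full precision) and
#'   `rd_2dp`, `ci_2dp` rounded to two decimals for display.
#' @export
unadjusted_rd_wald <- function(e1, n1, e0, n0, level = 0.95) {
  if (n1 < 1 || n0 < 1) tte_stop("'n' must be >= 1 in both arms")
  if (e1 < 0 || e1 > n1 || e0 < 0 || e0 > n0) {
    tte_stop("event counts must satisfy 0 <= e <= n")
  }
  p1 <- e1 / n1; p0 <- e0 / n0
  rd <- 100 * (p1 - p0)
  z <- qnorm(1 - (1 - level) / 2)
  se <- 100 * sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  ci <- rd + c(-1, 1) * z * se
  list(rd = rd, ci = ci, rd_2dp = round(rd, 2), ci_2dp = round(ci, 2))
}

#' Unadjusted discrete-time hazard ratio
#'
#' Pooled logistic model with arm and a month function only, all weights
#' 1, patient-clustered robust CI.
#'
#' @param pm PersonMonth table.
#' @param time_form Passed to [fit_pooled_logistic()].
#' @return As [hazard_ratio()].
#' @export
unadjusted_hr <- function(pm, time_form = "indicator") {
  hazard_ratio(fit_pooled_logistic(pm, time_form = time_form))
}

#' Analysis configuration
#'
#' Bundles every tunable of the emulation pipeline. The six sensitivity
#' switches map to: a 6-month grace period, inclusion of all stroke-risk
#' score levels, a 36-month horizon, exclusion of metastatic (distant
#' stage) cancer, exclusion of baseline thrombocytopenia, and weight
#' truncation at the 95th instead of 99th percentile.
#'
#' @param estimands Subset of `c("ITT", "PP")`.
#' @param outcomes Character vector of outcome names to analyze.
#' @param grace_period_months,horizon_months,score_threshold Design knobs.
#' @param truncation `"none"`, 95, or 99 (weight truncation percentile).
#' @param covariate_names Baseline covariates for the treatment,
#'   censoring, and outcome models.
#' @param tv_covariate_names Time-varying covariates for censoring models
#'   and per-protocol outcome models.
#' @param outcome_free `"per_outcome"` or `"global"` prior-event
#'   exclusion.
#' @param min_age Minimum index age.
#' @param n_imputations Completed datasets for missing covariates; with
#'   more than one, log-HRs are pooled by Rubin's rules.
#' @param gap_days Discontinuation gap.
#' @param deviation_at See [detect_discontinuation()].
#' @param tie_break See [assign_treatment_arm()].
#' @param bootstrap_reps Bootstrap replicates for adjusted-RD CIs
#'   (0 disables).
#' @param seed Seed for imputation and bootstrap.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(estimands = c("ITT", "PP"),
                            outcomes = "primary",
                            grace_period_months = 3L,
                            horizon_months = 12L,
                            score_threshold = 2,
                            truncation = 99,
                            covariate_names = character(0),
                            tv_covariate_names = character(0),
                            outcome_free = "per_outcome",
                            min_age = 66,
                            n_imputations = 1L,
                            gap_days = 30L,
                            deviation_at = "coverage_end",
                            tie_break = "error",
                            bootstrap_reps = 0L,
                            seed = 1L) {
  if (!length(estimands) || !all(estimands %in% c("ITT", "PP"))) {
    tte_stop("'estimands' must be a non-empty subset of c('ITT','PP')")
  }
  if (!length(outcomes)) tte_stop("at least one outcome is required")
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full emulation pipeline
#'
#' Executes, per outcome and estimand: imputation, arm assignment within
#' the grace period, sequential eligibility with attrition reporting,
#' person-month expansion, estimand-specific censoring, stabilized
#' IPTW x IPCW weighting with truncation, and the weighted pooled
#' logistic model -- yielding one effect-estimate row per
#' (estimand x outcome) with event counts, incidence rates, unadjusted
#' RD/HR, and adjusted HR (and RD when `bootstrap_reps > 0`,
#' otherwise point estimate only).
#'
#' @param config An [analysis_config()].
#' @param data A `tte_cohort` list (`baseline`, `fills`, `events`, `tv`)
#'   or a directory written by [write_cohort()].
#' @return List of class `tte_results`: `estimates` (data.table),
#'   `curves` (per estimand x outcome), `attrition` (per outcome),
#'   `weight_diagnostics`, `balance`.
#' @export
run_analysis <- function(config, data) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(data)) data <- read_cohort(data)
  check_cols(data$baseline, "patient_id", "baseline")
  baseline <- data.table::as.data.table(data$baseline)
  fills <- data.table::as.data.table(data$fills)
  events <- data.table::as.data.table(data$events)
  tv <- if (!is.null(data$tv)) data.table::as.data.table(data$tv) else NULL

  ## arm and start day are placeholders until assignment; drop them so the
  ## imputation step sees only genuine baseline fields
  pre <- intersect(c("arm", "treatment_start_day"), names(baseline))
  if (length(pre)) baseline <- baseline[, setdiff(names(baseline), pre),
                                        with = FALSE]
  imps <- impute_missing(baseline, n_imputations = config$n_imputations,
                         seed = config$seed)
  rules <- eligibility_rules(min_age = config$min_age,
                             score_threshold = config$score_threshold,
                             outcome_free = config$outcome_free)

  estimates <- list()
  curves <- list()
  attrition <- list()
  wdiag <- list()
  balance <- list()

  per_imp <- lapply(imps, function(bl) {
    cohort_all <- assign_treatment_arm(
      bl, fills, grace_period_months = config$grace_period_months,
      tie_break = config$tie_break)
    devs <- detect_discontinuation(
      cohort_all, fills, gap_days = config$gap_days,
      horizon_months = config$horizon_months,
      deviation_at = config$deviation_at)
    list(cohort_all = cohort_all, devs = devs)
  })

  time_form <- if (config$horizon_months <= 12L) "indicator" else "spline"

  for (oc in config$outcomes) {
    for (est in config$estimands) {
      acc <- list()
      for (m in seq_along(imps)) {
        cohort_all <- per_imp[[m]]$cohort_all
        devs <- per_imp[[m]]$devs
        elig <- apply_eligibility(cohort_all, fills, events, rules,
                                  outcome = oc)
        cohort <- elig$cohort
        if (m == 1L && est == config$estimands[[1L]]) {
          attrition[[oc]] <- elig$report
        }
        if (nrow(cohort) == 0L) {
          acc[[m]] <- NULL
          next
        }
        pm0 <- expand_person_months(cohort, events,
                                    horizon_months = config$horizon_months,
                                    outcome = oc, tv = tv)
        pm <- apply_estimand_censoring(pm0, devs, est)

        tm <- fit_treatment_model(cohort, config$covariate_names)
        iptw <- stabilized_iptw(tm)
        cens_models <- list(
          suppressWarnings(fit_censoring_model(
            pm, "ltfu", cohort, config$covariate_names,
            config$tv_covariate_names, time_form = "linear")))
        if (est == "PP") {
          cens_models <- c(cens_models, list(
            suppressWarnings(fit_censoring_model(
              pm, "deviation", cohort, config$covariate_names,
              config$tv_covariate_names, time_form = "linear"))))
        }
        ipcw <- stabilized_ipcw(cens_models, pm, cohort)
        ws <- combine_and_truncate(iptw, ipcw,
                                   percentile = config$truncation)
        out_covs <- config$covariate_names
        out_tv <- if (est == "PP") config$tv_covariate_names else character(0)
        fitm <- fit_pooled_logistic(pm, ws, cohort, out_covs, out_tv,
                                    time_form = time_form)
        acc[[m]] <- list(cohort = cohort, pm = pm, iptw = iptw, ws = ws,
                         fitm = fitm, devs = devs)
      }
      acc <- Filter(Negate(is.null), acc)
      key <- paste(est, oc, sep = ".")
      if (!length(acc)) {
        estimates[[key]] <- empty_estimate_row(est, oc)
        next
      }
      estimates[[key]] <- summarize_combo(acc, est, oc, config)
      first <- acc[[1L]]
      curves[[key]] <- standardized_risk_curves(
        first$fitm, first$cohort, weights = first$iptw,
        horizon = config$horizon_months)
      if (est == config$estimands[[1L]]) {
        wdiag[[key]] <- weight_diagnostics(first$ws)
        if (length(config$covariate_names)) {
          w_pat <- merge(first$cohort[, list(patient_id)], first$iptw,
                         by = "patient_id", sort = FALSE)
          balance[[key]] <- smd_balance(first$cohort,
                                        config$covariate_names,
                                        w_pat$iptw_stab)
        }
      }
    }
  }
  structure(list(estimates = data.table::rbindlist(estimates,
                                                   use.names = TRUE),
                 curves = curves, attrition = attrition,
                 weight_diagnostics = wdiag, balance = balance,
                 config = config),
            class = "tte_results")
}

#' Pool one (estimand, outcome) combination across imputations
#' @noRd
summarize_combo <- function(acc, est, oc, config) {
  m <- length(acc)
  logs <- vapply(acc, function(a) a$fitm$arm_est, numeric(1))
  ses <- vapply(acc, function(a) a$fitm$arm_se, numeric(1))
  flagged <- any(vapply(acc, function(a) a$fitm$flagged, logical(1)))
  if (flagged || anyNA(logs)) {
    hr <- NA_real_; hr_ci <- c(0, Inf)
  } else if (m == 1L) {
    hh <- hazard_ratio(acc[[1L]]$fitm)
    hr <- hh$hr; hr_ci <- hh$ci
  } else {
    ## Rubin's rules on the log-HR
    qbar <- mean(logs); wvar_ <- mean(ses^2); bvar <- var(logs)
    tvar <- wvar_ + (1 + 1 / m) * bvar
    hr <- exp(qbar)
    hr_ci <- exp(qbar + c(-1, 1) * qnorm(0.975) * sqrt(tvar))
  }

  a1 <- acc[[1L]]
  pm <- a1$pm
  byarm <- pm[, list(pm_total = .N, events = sum(event)), by = arm]
  getv <- function(tab, armv, col) {
    v <- tab[[col]][tab$arm == armv]
    if (length(v)) v else 0L
  }
  nA <- sum(a1$cohort$arm == "A"); nB <- sum(a1$cohort$arm == "B")
  eA <- getv(byarm, "A", "events"); eB <- getv(byarm, "B", "events")
  pmA <- getv(byarm, "A", "pm_total"); pmB <- getv(byarm, "B", "pm_total")

  cv <- standardized_risk_curves(a1$fitm, a1$cohort, weights = a1$iptw,
                                 horizon = config$horizon_months)
  if (config$bootstrap_reps >= 2) {
    refit <- make_refit_fun(a1, est, oc, config)
    rdres <- risk_difference(cv, config$horizon_months,
                             bootstrap_reps = config$bootstrap_reps,
                             seed = config$seed, refit_fun = refit)
  } else {
    rdres <- risk_difference(cv, config$horizon_months)
  }
  urd <- unadjusted_rd_wald(eA, nA, eB, nB)
  uhr <- tryCatch(unadjusted_hr(pm), error = function(e) {
    list(hr = NA_real_, ci = c(NA_real_, NA_real_))
  })

  data.table::data.table(
    estimand = est, outcome = oc,
    n_A = nA, n_B = nB, events_A = eA, events_B = eB,
    pct_A = round(100 * eA / max(nA, 1L), 2),
    pct_B = round(100 * eB / max(nB, 1L), 2),
    person_years_A = pmA * 30 / 365.25,
    person_years_B = pmB * 30 / 365.25,
    ir_A = if (pmA > 0) incidence_rate(eA, pmA) else NA_real_,
    ir_B = if (pmB > 0) incidence_rate(eB, pmB) else NA_real_,
    unadj_rd = urd$rd, unadj_rd_lo = urd$ci[1L], unadj_rd_hi = urd$ci[2L],
    unadj_hr = uhr$hr, unadj_hr_lo = uhr$ci[1L], unadj_hr_hi = uhr$ci[2L],
    hr = hr, hr_lo = hr_ci[1L], hr_hi = hr_ci[2L],
    rd = rdres$rd, rd_lo = rdres$ci[1L], rd_hi = rdres$ci[2L],
    flagged = flagged)
}

#' Bootstrap closure: resample patients, refit weights and model
#' @noRd
make_refit_fun <- function(a, est, oc, config) {
  cohort <- a$cohort
  pm <- a$pm
  function() {
    ids <- sample(cohort$patient_id, nrow(cohort), replace = TRUE)
    idx <- data.table::data.table(patient_id = ids,
                                  new_id = seq_along(ids))
    bc <- merge(idx, cohort, by = "patient_id", sort = FALSE)
    bc[, patient_id := new_id]; bc[, new_id := NULL]
    bpm <- merge(idx, pm, by = "patient_id", sort = FALSE,
                 allow.cartesian = TRUE)
    bpm[, patient_id := new_id]; bpm[, new_id := NULL]
    tm <- fit_treatment_model(bc, config$covariate_names)
    iptw <- stabilized_iptw(tm)
    cens <- list(suppressWarnings(fit_censoring_model(
      bpm, "ltfu", bc, config$covariate_names,
      config$tv_covariate_names, time_form = "linear")))
    if (est == "PP") {
      cens <- c(cens, list(suppressWarnings(fit_censoring_model(
        bpm, "deviation", bc, config$covariate_names,
        config$tv_covariate_names, time_form = "linear"))))
    }
    ipcw <- stabilized_ipcw(cens, bpm, bc)
    ws <- combine_and_truncate(iptw, ipcw, percentile = config$truncation)
    out_tv <- if (est == "PP") config$tv_covariate_names else character(0)
    fitm <- fit_pooled_logistic(bpm, ws, bc, config$covariate_names,
                                out_tv,
                                time_form = if (config$horizon_months <= 12L)
                                  "indicator" else "spline")
    standardized_risk_curves(fitm, bc, weights = iptw,
                             horizon = config$horizon_months)
  }
}

#' @noRd
empty_estimate_row <- function(est, oc) {
  data.table::data.table(
    estimand = est, outcome = oc, n_A = 0L, n_B = 0L,
    events_A = 0L, events_B = 0L, pct_A = NA_real_, pct_B = NA_real_,
    person_years_A = 0, person_years_B = 0, ir_A = NA_real_,
    ir_B = NA_real_, unadj_rd = NA_real_, unadj_rd_lo = NA_real_,
    unadj_rd_hi = NA_real_, unadj_hr = NA_real_, unadj_hr_lo = NA_real_,
    unadj_hr_hi = NA_real_, hr = NA_real_, hr_lo = NA_real_,
    hr_hi = NA_real_, rd = NA_real_, rd_lo = NA_real_, rd_hi = NA_real_,
    flagged = TRUE)
}

#' Re-run the weighted analysis within subgroup strata
#'
#' Weights are re-estimated within each stratum (internal-validity
#' choice; a global-weight variant would subset instead). Strata where
#' the model is unidentifiable (zero events in an arm) come back flagged
#' rather than estimated.
#'
#' @param config An [analysis_config()].
#' @param data A `tte_cohort` list or directory.
#' @param axis One of `cancer_type`, `cancer_status`, `cancer_stage`,
#'   `tumor_grade`.
#' @return data.table of estimate rows with a `stratum` column.
#' @export
run_subgroups <- function(config, data, axis) {
  if (!axis %in% c("cancer_type", "cancer_status", "cancer_stage",
                   "tumor_grade")) {
    tte_stop("unknown subgroup axis '", axis, "'")
  }
  if (is.character(data)) data <- read_cohort(data)
  check_cols(data$baseline, axis, "baseline")
  strata <- sort(unique(data$baseline[[axis]]))
  rows <- lapply(strata, function(s) {
    sub <- data
    keep <- data$baseline[[axis]] == s
    sub$baseline <- data$baseline[keep, ]
    res <- tryCatch(run_analysis(config, sub),
                    error = function(e) NULL)
    if (is.null(res)) {
      est <- data.table::rbindlist(lapply(config$estimands, function(e2) {
        data.table::rbindlist(lapply(config$outcomes, function(o2) {
          empty_estimate_row(e2, o2)
        }))
      }))
    } else {
      est <- res$estimates
    }
    est[, stratum := paste(axis, s, sep = "=")]
    est
  })
  data.table::rbindlist(rows)
}

#' Run one named sensitivity analysis
#'
#' @param config The main [analysis_config()].
#' @param data A `tte_cohort` list or directory.
#' @param switch One of `grace6`, `all_scores`, `horizon36`,
#'   `drop_metastatic`, `drop_thrombocytopenia`, `truncate95`.
#' @return A `tte_results` list as from [run_analysis()].
#' @export
run_sensitivity <- function(config, data,
                            switch = c("grace6", "all_scores", "horizon36",
                                       "drop_metastatic",
                                       "drop_thrombocytopenia",
                                       "truncate95")) {
  switch <- match.arg(switch)
  if (is.character(data)) data <- read_cohort(data)
  cfg <- config
  if (switch == "grace6") cfg$grace_period_months <- 6L
  if (switch == "all_scores") cfg$score_threshold <- NA
  if (switch == "horizon36") cfg$horizon_months <- 36L
  if (switch == "truncate95") cfg$truncation <- 95
  if (switch == "drop_metastatic") {
    data$baseline <- data$baseline[data$baseline$cancer_stage != "distant", ]
  }
  if (switch == "drop_thrombocytopenia") {
    data$baseline <- data$baseline[!(data$baseline$thrombocytopenia %in% TRUE), ]
  }
  run_analysis(cfg, data)
}

#' Render the estimates table with small-cell suppression
#'
#' Counts below 11 are rendered as an en dash in the returned character
#' table when suppression is on; the machine-readable estimates are
#' never altered.
#'
#' @param estimates The `estimates` table of a `tte_results`.
#' @param suppress Apply small-cell suppression (default TRUE).
#' @param cell_min Suppression threshold (default 11).
#' @return A data.frame of formatted strings.
#' @export
render_estimates <- function(estimates, suppress = TRUE, cell_min = 11L) {
  fmt_n <- function(x) {
    ifelse(suppress & x > 0L & x < cell_min, "–",
           format(x, trim = TRUE))
  }
  fmt2 <- function(x) ifelse(is.na(x), "–", sprintf("%.2f", x))
  data.frame(
    estimand = estimates$estimand, outcome = estimates$outcome,
    events_A = fmt_n(estimates$events_A),
    events_B = fmt_n(estimates$events_B),
    ir_A = fmt2(estimates$ir_A), ir_B = fmt2(estimates$ir_B),
    unadj_rd = sprintf("%s (%s, %s)", fmt2(estimates$unadj_rd),
                       fmt2(estimates$unadj_rd_lo),
                       fmt2(estimates$unadj_rd_hi)),
    unadj_hr = sprintf("%s (%s, %s)", fmt2(estimates$unadj_hr),
                       fmt2(estimates$unadj_hr_lo),
                       fmt2(estimates$unadj_hr_hi)),
    adj_hr = sprintf("%s (%s, %s)", fmt2(estimates$hr),
                     fmt2(estimates$hr_lo), fmt2(estimates$hr_hi)),
    adj_rd = sprintf("%s (%s, %s)", fmt2(estimates$rd),
                     fmt2(estimates$rd_lo), fmt2(estimates$rd_hi)),
    stringsAsFactors = FALSE)
}
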