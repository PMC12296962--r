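#' Detect treatment discontinuation and switching from fill chains
#'
#' Walks each patient's same-class fills from treatment start, extending a
#' coverage interval by each fill's days' supply (overlapping fills
#' stockpile additively; a new fill after a lapse shorter than `gap_days`
#' restarts coverage at the fill day). A gap of `gap_days` or more between
#' the end of coverage and the next fill -- or between the end of coverage
#' and the end of follow-up when there is no next fill -- marks
#' discontinuation; any fill of the opposite drug class on or after
#' treatment start marks a switch. The deviation day is the earlier of the
#' two.
#'
#' @param cohort PatientBaseline table with `arm` and
#'   `treatment_start_day` assigned.
#' @param fills PrescriptionFill table.
#' @param gap_days Gap defining discontinuation (default 30).
#' @param horizon_months Administrative horizon defining follow-up end for
#'   the trailing-gap check.
#' @param deviation_at `"coverage_end"` dates the deviation at the first
#'   uncovered day; `"gap_complete"` dates it `gap_days` later, once the
#'   gap criterion has been met.
#' @return data.table `patient_id`, `deviation_day` (`NA` if adherent),
#'   `reason` (`"discontinuation"`, `"switch"`, or `NA`).
#' @export
detect_discontinuation <- function(cohort, fills, gap_days = 30L,
                                   horizon_months = 12L,
                                   deviation_at = c("coverage_end",
                                                    "gap_complete")) {
  deviation_at <- match.arg(deviation_at)
  check_cols(cohort, c("patient_id", "arm", "treatment_start_day"), "cohort")
  check_cols(fills, c("patient_id", "day", "drug_class", "days_supply"),
             "fills")
  fills <- data.table::as.data.table(fills)
  if (any(fills$days_supply <= 0)) tte_stop("'days_supply' must be positive")
  offset <- if (deviation_at == "coverage_end") 0L else as.integer(gap_days)

  f <- merge(fills,
             data.table::as.data.table(cohort)[, list(
               patient_id, arm, treatment_start_day)],
             by = "patient_id")
  f <- f[day >= treatment_start_day]
  data.table::setorder(f, patient_id, day)

  out <- f[, {
    fu_end <- treatment_start_day[1L] + 30L * horizon_months
    same <- which(drug_class == arm[1L])
    other <- which(drug_class != arm[1L])
    switch_day <- if (length(other)) day[other[1L]] else NA_integer_
    dev <- NA_integer_
    if (length(same)) {
      cov_end <- day[same[1L]] + days_supply[same[1L]]
      for (k in same[-1L]) {
        if (day[k] <= cov_end) {
          cov_end <- cov_end + days_supply[k]          # stockpiling
        } else if (day[k] - cov_end < gap_days) {
          cov_end <- day[k] + days_supply[k]           # short lapse
        } else {
          dev <- as.integer(cov_end + offset)
          break
        }
      }
      if (is.na(dev) && fu_end - cov_end >= gap_days) {
        dev <- as.integer(cov_end + offset)
      }
    }
    reason <- NA_character_
    if (!is.na(switch_day) && (is.na(dev) || switch_day < dev)) {
      dev <- switch_day
      reason <- "switch"
    } else if (!is.na(dev)) {
      reason <- "discontinuation"
    }
    list(deviation_day = dev, reason = reason)
  }, by = patient_id]

  out <- merge(data.table::data.table(patient_id = cohort$patient_id), out,
               by = "patient_id", all.x = TRUE)
  out[]
}

#' Expand an analysis cohort into person-month records
#'
#' One record per patient per 30-day month of follow-up, month 0 starting
#' at `treatment_start_day` and month k covering days `[30k, 30(k+1))`
#' from it. Follow-up ends at the earliest of: the analyzed outcome's
#' event, death, loss to follow-up, or the administrative horizon; the
#' terminal record carries the corresponding flag (same-day ties resolved
#' event > death > ltfu > administrative). Time-varying covariates, when
#' supplied, are merged by follow-up month.
#'
#' @param cohort PatientBaseline table with arms assigned.
#' @param events Event table; rows with `type == outcome` are outcome
#'   events, `"death"`/`"ltfu"` rows are censoring events.
#' @param horizon_months Administrative horizon (default 12).
#' @param outcome Outcome name to analyze.
#' @param tv Optional time-varying covariate table
#'   (`patient_id`, `month`, covariates).
#' @return PersonMonth `data.table`: `patient_id`, `month`, `arm`,
#'   `treatment_start_day`, `event`, `censor_admin`, `censor_death`,
#'   `censor_ltfu`, `censor_deviation` plus any tv columns.
#' @export
expand_person_months <- function(cohort, events, horizon_months = 12L,
                                 outcome = "primary", tv = NULL) {
  if (horizon_months < 1) tte_stop("'horizon_months' must be >= 1")
  check_cols(cohort, c("patient_id", "arm", "treatment_start_day"), "cohort")
  check_cols(events, c("patient_id", "type", "day"), "events")
  cohort <- data.table::as.data.table(cohort)
  if (any(!cohort$arm %in% c("A", "B"))) {
    tte_stop("all patients must have arm 'A' or 'B' (drop arm = 'none')")
  }
  events <- data.table::as.data.table(events)
  n <- nrow(cohort)
  start <- cohort$treatment_start_day
  ids <- cohort$patient_id
  H <- as.integer(horizon_months)

  day_of <- function(ev) {
    ev <- ev[ev$patient_id %in% ids, ]
    ev <- ev[order(ev$patient_id, ev$day), ]
    first <- ev[!duplicated(ev$patient_id), ]
    d <- rep(Inf, n)
    d[match(first$patient_id, ids)] <- first$day
    d
  }
  d_event <- day_of(events[type == outcome])
  if (any(d_event < start)) {
    tte_stop("outcome event before treatment start for patient ",
             ids[which(d_event < start)[1L]],
             "; exclude such patients upstream")
  }
  d_death <- day_of(events[type == "death"])
  d_ltfu <- day_of(events[type == "ltfu"])
  d_admin <- start + 30 * H
  ## candidates at or beyond the horizon never terminate follow-up
  d_event[d_event - start >= 30 * H] <- Inf
  d_death[d_death - start >= 30 * H] <- Inf
  d_death[d_death < start] <- Inf
  d_ltfu[d_ltfu - start >= 30 * H] <- Inf
  d_ltfu[d_ltfu < start] <- Inf

  days <- cbind(d_event, d_death, d_ltfu, d_admin)
  pick <- max.col(-days, ties.method = "first")  # earliest day, ties by
                                                 # column priority
  d_min <- days[cbind(seq_len(n), pick)]
  t_month <- as.integer(pmin((d_min - start) %/% 30, H - 1L))

  pm <- data.table::data.table(
    patient_id = rep(ids, t_month + 1L),
    month = as.integer(sequence(t_month + 1L) - 1L),
    arm = rep(cohort$arm, t_month + 1L),
    treatment_start_day = rep(as.integer(start), t_month + 1L))
  terminal <- cumsum(t_month + 1L)
  pm[, `:=`(event = FALSE, censor_admin = FALSE, censor_death = FALSE,
            censor_ltfu = FALSE, censor_deviation = FALSE)]
  flag_col <- c("event", "censor_death", "censor_ltfu", "censor_admin")[pick]
  for (fc in unique(flag_col)) {
    data.table::set(pm, i = terminal[flag_col == fc], j = fc, value = TRUE)
  }
  if (!is.null(tv)) {
    check_cols(tv, c("patient_id", "month"), "tv")
    pm <- merge(pm, data.table::as.data.table(tv),
                by = c("patient_id", "month"), all.x = TRUE, sort = TRUE)
  }
  data.table::setorder(pm, patient_id, month)
  pm[]
}

#' Apply estimand-specific artificial censoring
#'
#' Under the intention-to-treat estimand the table is returned unchanged.
#' Under per-protocol, follow-up is truncated at each deviating patient's
#' deviation month: later records are removed and the new terminal record
#' carries `censor_deviation`, unless a higher-priority terminal already
#' falls in or before that month (priority event > death > ltfu >
#' deviation > administrative).
#'
#' @param pm PersonMonth table from [expand_person_months()].
#' @param deviations Deviation table from [detect_discontinuation()].
#' @param estimand `"ITT"` or `"PP"`.
#' @return A PersonMonth table.
#' @export
apply_estimand_censoring <- function(pm, deviations, estimand) {
  if (!estimand %in% c("ITT", "PP")) {
    tte_stop("unknown estimand '", estimand, "' (use 'ITT' or 'PP')")
  }
  pm <- data.table::as.data.table(pm)
  if (estimand == "ITT") return(data.table::copy(pm))
  check_cols(deviations, c("patient_id", "deviation_day"), "deviations")
  dev <- data.table::as.data.table(deviations)[!is.na(deviation_day)]
  out <- merge(pm, dev[, list(patient_id, deviation_day)],
               by = "patient_id", all.x = TRUE, sort = TRUE)
  out[, dev_month := (deviation_day - treatment_start_day) %/% 30L]
  ## drop records strictly after the deviation month
  out <- out[is.na(dev_month) | month <= dev_month]
  ## re-flag the new terminal record
  at_dev <- !is.na(out$dev_month) & out$month == out$dev_month
  keep_existing <- out$event | out$censor_death | out$censor_ltfu
  set_dev <- at_dev & !keep_existing
  data.table::set(out, i = which(set_dev), j = "censor_deviation",
                  value = TRUE)
  data.table::set(out, i = which(set_dev), j = "censor_admin", value = FALSE)
  out[, c("deviation_day", "dev_month") := NULL]
  data.table::setorder(out, patient_id, month)
  out[]
}
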