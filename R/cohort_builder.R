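#' Assign treatment arms by the first fill inside the grace period
#'
#' The arm is the drug class of the chronologically first fill with
#' `0 <= day < 30 * grace_period_months`; that fill's day becomes the
#' patient's `treatment_start_day`, where follow-up starts. Patients with
#' no qualifying fill get `arm = "none"` and are dropped from the returned
#' cohort (their count is kept in the `n_unassigned` attribute). Two fills
#' of different classes on the same first day are ambiguous and raise an
#' error unless `tie_break = "comparator"` deterministically assigns the
#' comparator arm B.
#'
#' @param patients PatientBaseline table.
#' @param fills PrescriptionFill table (`patient_id`, `day`, `drug_class`,
#'   `days_supply`).
#' @param grace_period_months Grace period in months (>= 1).
#' @param tie_break `"error"` (default) or `"comparator"`.
#' @param drop_unassigned Drop patients with no qualifying fill (default).
#' @return The cohort with `arm` and `treatment_start_day` filled in,
#'   invariant to the row order of `fills`.
#' @export
assign_treatment_arm <- function(patients, fills, grace_period_months = 3L,
                                 tie_break = c("error", "comparator"),
                                 drop_unassigned = TRUE) {
  tie_break <- match.arg(tie_break)
  if (grace_period_months < 1) tte_stop("'grace_period_months' must be >= 1")
  check_cols(fills, c("patient_id", "day", "drug_class"), "fills")
  check_cols(patients, "patient_id", "patients")
  fills <- data.table::as.data.table(fills)
  qual <- fills[day >= 0L & day < 30L * grace_period_months]
  data.table::setorder(qual, patient_id, day, drug_class)
  first <- qual[, {
    classes <- unique(drug_class[day == day[1L]])
    if (length(classes) > 1L) {
      if (tie_break == "error") {
        tte_stop("patient ", .BY[[1L]], ": same-day first fills of both ",
                 "drug classes; set tie_break = 'comparator' to resolve")
      }
      classes <- "B"
    }
    list(arm = classes, treatment_start_day = day[1L])
  }, by = patient_id]

  out <- data.table::as.data.table(patients)
  old <- intersect(c("arm", "treatment_start_day"), names(out))
  if (length(old)) out[, (old) := NULL]
  out <- merge(out, first, by = "patient_id", all.x = TRUE, sort = TRUE)
  unassigned <- is.na(out$arm)
  out[unassigned, arm := "none"]
  n_unassigned <- sum(unassigned)
  if (drop_unassigned) out <- out[arm != "none"]
  data.table::setattr(out, "n_unassigned", n_unassigned)
  out[]
}

#' Default eligibility rule set
#'
#' Returns the ordered list of eligibility criteria emulating a new-user
#' anticoagulant trial in an elderly cancer cohort: minimum age 66, prior
#' cancer record, continuous enrollment, stroke-risk score threshold
#' (CHA2DS2-VASc >= 2; `NA` means all levels, the sensitivity reading),
#' an oral-anticoagulant washout over the baseline period, no
#' contraindications, no stroke within 14 days, no major bleeding/surgery
#' within 30 days, no end-stage renal disease, and outcome-free before
#' treatment start.
#'
#' @param min_age Minimum index age.
#' @param score_threshold CHA2DS2-VASc threshold, or `NA` for all levels.
#' @param outcome_free `"per_outcome"` excludes only patients with a prior
#'   event of the analyzed outcome; `"global"` excludes a prior event of
#'   any outcome type.
#' @return A list of rule descriptors consumed by [apply_eligibility()].
#' @export
eligibility_rules <- function(min_age = 66, score_threshold = 2,
                              outcome_free = c("per_outcome", "global")) {
  outcome_free <- match.arg(outcome_free)
  list(
    list(name = "age >= minimum", type = "min_age", value = min_age),
    list(name = "prior cancer record", type = "prior_cancer"),
    list(name = "continuous enrollment", type = "flag_true",
         field = "continuous_enrollment"),
    list(name = "stroke-risk score threshold", type = "score_threshold",
         value = score_threshold),
    list(name = "anticoagulant washout", type = "oac_washout"),
    list(name = "no contraindication", type = "flag_false",
         field = "contraindication"),
    list(name = "no stroke within 14 days", type = "flag_false",
         field = "recent_stroke_14d"),
    list(name = "no recent bleeding/surgery", type = "flag_false",
         field = "recent_bleed_30d"),
    list(name = "no end-stage renal disease", type = "flag_false",
         field = "renal_failure"),
    list(name = "outcome-free before treatment start", type = "outcome_free",
         mode = outcome_free))
}

#' Apply eligibility criteria sequentially and report attrition
#'
#' Criteria are applied in the given order; the report has one row per
#' criterion with the counts before, excluded, and after, chaining into an
#' attrition flowchart. Because each criterion is a pure row predicate,
#' permuting the order changes intermediate rows but never the final
#' cohort.
#'
#' @param patients PatientBaseline table (with `arm` and
#'   `treatment_start_day` if the outcome-free rule is active).
#' @param fills PrescriptionFill table (for the washout rule).
#' @param events Event table (for the outcome-free rule).
#' @param rules Rule list from [eligibility_rules()] (or a subset).
#' @param outcome Outcome name for the per-outcome outcome-free rule.
#' @return A list with `cohort` (eligible patients) and `report`
#'   (data.table: criterion, n_before, n_excluded, n_after).
#' @export
apply_eligibility <- function(patients, fills, events,
                              rules = eligibility_rules(),
                              outcome = NULL) {
  cur <- data.table::as.data.table(patients)
  fills <- data.table::as.data.table(fills)
  events <- data.table::as.data.table(events)
  report <- vector("list", length(rules))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    n_before <- nrow(cur)
    keep <- switch(
      r$type,
      min_age = {
        check_cols(cur, "age_at_index", "patients")
        cur$age_at_index >= r$value
      },
      prior_cancer = {
        check_cols(cur, "months_since_cancer_dx", "patients")
        !is.na(cur$months_since_cancer_dx) & cur$months_since_cancer_dx >= 0
      },
      flag_true = {
        check_cols(cur, r$field, "patients")
        cur[[r$field]] %in% TRUE
      },
      flag_false = {
        check_cols(cur, r$field, "patients")
        !(cur[[r$field]] %in% TRUE)
      },
      score_threshold = {
        check_cols(cur, "cha2ds2_vasc", "patients")
        if (is.na(r$value)) rep(TRUE, nrow(cur))
        else cur$cha2ds2_vasc >= r$value
      },
      oac_washout = {
        baseline_users <- unique(fills[day < 0L, patient_id])
        flagged <- if ("prior_oac" %in% names(cur)) cur$prior_oac %in% TRUE
                   else FALSE
        !(cur$patient_id %in% baseline_users) & !flagged
      },
      outcome_free = {
        check_cols(cur, "treatment_start_day", "patients")
        types <- if (identical(r$mode, "global")) {
          setdiff(unique(events$type), c("death", "ltfu"))
        } else {
          if (is.null(outcome)) {
            tte_stop("outcome-free rule in per-outcome mode needs 'outcome'")
          }
          outcome
        }
        pre <- merge(events[type %in% types],
                     cur[, list(patient_id, treatment_start_day)],
                     by = "patient_id")
        bad <- unique(pre[day < treatment_start_day, patient_id])
        !(cur$patient_id %in% bad)
      },
      tte_stop("unknown eligibility rule type '", r$type, "'"))
    cur <- cur[keep]
    report[[k]] <- data.table::data.table(
      criterion = r$name, n_before = n_before,
      n_excluded = n_before - nrow(cur), n_after = nrow(cur))
  }
  list(cohort = cur[], report = data.table::rbindlist(report))
}

#' Pretty-print an attrition report
#'
#' @param report The report component of [apply_eligibility()].
#' @return The report, invisibly; prints a flowchart-style text table.
#' @export
print_attrition <- function(report) {
  cat(sprintf("%-40s %9s %9s %9s\n", "criterion", "before", "excluded",
              "after"))
  for (i in seq_len(nrow(report))) {
    cat(sprintf("%-40s %9d %9d %9d\n", report$criterion[i],
                report$n_before[i], report$n_excluded[i], report$n_after[i]))
  }
  invisible(report)
}
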