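# Hand-built micro-fixtures used across test files. All tables are tiny
# and constructed in code; days are integers from each patient's index.

make_baseline <- function(n, arm = rep("A", n), start = rep(0L, n)) {
  data.table::data.table(
    patient_id = seq_len(n), index_day = 0L,
    age_at_index = 70, sex = "male",
    months_since_cancer_dx = 12, cha2ds2_vasc = 3L, has_bled = 1L,
    continuous_enrollment = TRUE, prior_oac = FALSE,
    contraindication = FALSE, recent_stroke_14d = FALSE,
    recent_bleed_30d = FALSE, renal_failure = FALSE,
    thrombocytopenia = FALSE,
    cancer_type = "breast", cancer_status = "history",
    cancer_stage = "local", tumor_grade = "II",
    arm = arm, treatment_start_day = start)
}

make_fills <- function(patient_id, day, drug_class, days_supply = 30L) {
  data.table::data.table(patient_id = patient_id, day = as.integer(day),
                         drug_class = drug_class,
                         days_supply = as.integer(days_supply))
}

make_events <- function(patient_id = integer(0), type = character(0),
                        day = integer(0)) {
  data.table::data.table(patient_id = as.integer(patient_id), type = type,
                         day = as.integer(day))
}

# Assign arms and drop patients with a pre-treatment event of the given
# outcome (the exclusion expand_person_months() requires upstream)
eligible_arms <- function(co, outcome = "primary") {
  arms <- assign_treatment_arm(co$baseline, co$fills)
  rules <- list(list(name = "of", type = "outcome_free",
                     mode = "per_outcome"))
  apply_eligibility(arms, co$fills, co$events, rules,
                    outcome = outcome)$cohort
}

# A small generated cohort shared by pipeline-level tests
small_pipeline_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 1500L, seed = 404L)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})
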