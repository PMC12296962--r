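test_that("arm follows the chronologically first qualifying fill", {
  bl <- make_baseline(3)
  fills <- make_fills(c(1L, 2L, 3L, 3L), c(10L, 100L, 5L, 20L),
                      c("A", "A", "B", "A"))
  out <- assign_treatment_arm(bl, fills, grace_period_months = 3L)
  ## patient 1: single fill day 10 -> arm A, start 10
  expect_identical(out[patient_id == 1, arm], "A")
  expect_identical(out[patient_id == 1, treatment_start_day], 10L)
  ## patient 3: B at day 5 precedes A at day 20 -> arm B, start 5
  expect_identical(out[patient_id == 3, arm], "B")
  expect_identical(out[patient_id == 3, treatment_start_day], 5L)
  ## patient 2: only fill at day 100 is outside the 3-month grace -> dropped
  expect_false(2L %in% out$patient_id)
  expect_identical(attr(out, "n_unassigned"), 1L)
  ## with a 6-month grace the same fill qualifies
  out6 <- assign_treatment_arm(bl, fills, grace_period_months = 6L)
  expect_identical(out6[patient_id == 2, arm], "A")
  expect_identical(out6[patient_id == 2, treatment_start_day], 100L)
})

test_that("assignment is invariant to fill row order and idempotent", {
  bl <- make_baseline(2)
  fills <- make_fills(c(1L, 1L, 2L, 2L), c(40L, 3L, 25L, 8L),
                      c("B", "A", "A", "B"))
  out1 <- assign_treatment_arm(bl, fills)
  out2 <- assign_treatment_arm(bl, fills[c(4, 1, 3, 2)])
  expect_identical(as.data.frame(out1), as.data.frame(out2))
  out3 <- assign_treatment_arm(out1, fills)
  expect_identical(as.data.frame(out1), as.data.frame(out3))
})

test_that("same-day fills of both classes error unless tie-broken to comparator", {
  bl <- make_baseline(1)
  fills <- make_fills(c(1L, 1L), c(4L, 4L), c("A", "B"))
  expect_error(assign_treatment_arm(bl, fills), "same-day")
  out <- assign_treatment_arm(bl, fills, tie_break = "comparator")
  expect_identical(out$arm, "B")
})

test_that("baseline anticoagulant use is excluded by the washout rule", {
  bl <- make_baseline(2)
  fills <- make_fills(c(1L, 2L), c(-40L, 10L), c("A", "A"))
  res <- apply_eligibility(bl, fills, make_events(),
                           rules = list(list(name = "washout",
                                             type = "oac_washout")))
  expect_identical(res$cohort$patient_id, 2L)
  expect_identical(res$report$n_excluded, 1L)
})

test_that("score threshold excludes low scores; the all-levels reading retains them", {
  bl <- make_baseline(2)
  bl$cha2ds2_vasc <- c(1L, 4L)
  rules2 <- list(list(name = "score", type = "score_threshold", value = 2))
  res <- apply_eligibility(bl, make_fills(integer(0), integer(0),
                                          character(0)),
                           make_events(), rules = rules2)
  expect_identical(res$cohort$patient_id, 2L)
  rules_all <- list(list(name = "score", type = "score_threshold",
                         value = NA))
  res_all <- apply_eligibility(bl, make_fills(integer(0), integer(0),
                                              character(0)),
                               make_events(), rules = rules_all)
  expect_identical(res_all$cohort$patient_id, c(1L, 2L))
})

test_that("an all-pass cohort reports zero exclusions on every row", {
  bl <- make_baseline(10)
  fills <- make_fills(1:10, rep(5L, 10), rep("A", 10))
  res <- apply_eligibility(bl, fills, make_events(), outcome = "primary")
  expect_true(all(res$report$n_excluded == 0L))
  expect_true(all(res$report$n_after[nrow(res$report)] == 10L))
  ## report rows chain
  expect_identical(res$report$n_after[-nrow(res$report)],
                   res$report$n_before[-1L])
  expect_identical(res$report$n_after,
                   res$report$n_before - res$report$n_excluded)
})

test_that("outcome-free exclusion is per-outcome by default, global on request", {
  bl <- make_baseline(2)
  ev <- make_events(1L, "stroke", 3L)  # before start (day 0? start 0)
  bl$treatment_start_day <- c(10L, 10L)
  rules_po <- list(list(name = "of", type = "outcome_free",
                        mode = "per_outcome"))
  res_stroke <- apply_eligibility(bl, make_fills(integer(0), integer(0),
                                                 character(0)),
                                  ev, rules_po, outcome = "stroke")
  expect_identical(res_stroke$cohort$patient_id, 2L)
  res_bleed <- apply_eligibility(bl, make_fills(integer(0), integer(0),
                                                character(0)),
                                 ev, rules_po, outcome = "bleed")
  expect_identical(res_bleed$cohort$patient_id, c(1L, 2L))
  rules_gl <- list(list(name = "of", type = "outcome_free",
                        mode = "global"))
  res_gl <- apply_eligibility(bl, make_fills(integer(0), integer(0),
                                             character(0)),
                              ev, rules_gl, outcome = "bleed")
  expect_identical(res_gl$cohort$patient_id, 2L)
})

test_that("permuting criterion order changes the report, not the final cohort", {
  co <- small_pipeline_cohort()
  arms <- assign_treatment_arm(co$baseline, co$fills)
  rules <- eligibility_rules()
  res1 <- apply_eligibility(arms, co$fills, co$events, rules,
                            outcome = "primary")
  res2 <- apply_eligibility(arms, co$fills, co$events, rev(rules),
                            outcome = "primary")
  expect_setequal(res1$cohort$patient_id, res2$cohort$patient_id)
  expect_false(identical(res1$report$criterion, res2$report$criterion))
})

test_that("a rule naming an absent field fails with the field name", {
  bl <- make_baseline(2)
  bl$continuous_enrollment <- NULL
  expect_error(
    apply_eligibility(bl, make_fills(integer(0), integer(0), character(0)),
                      make_events(),
                      rules = list(list(name = "ce", type = "flag_true",
                                        field = "continuous_enrollment"))),
    "continuous_enrollment")
})

test_that("empty result is permitted and still reported", {
  bl <- make_baseline(2)
  bl$age_at_index <- c(60, 62)
  res <- apply_eligibility(bl, make_fills(integer(0), integer(0),
                                          character(0)),
                           make_events(),
                           rules = list(list(name = "age", type = "min_age",
                                             value = 66)))
  expect_identical(nrow(res$cohort), 0L)
  expect_identical(res$report$n_after, 0L)
})
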