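test_that("person-month expansion follows the half-open 30-day binning", {
  bl <- make_baseline(3, arm = c("A", "A", "B"))
  ## p1: event day 75 -> months 0,1 clean, month 2 event
  ## p2: fully followed -> 12 records, terminal admin
  ## p3: death day 30 exactly -> month 1 carries the death flag
  ev <- make_events(c(1L, 3L), c("primary", "death"), c(75L, 30L))
  pm <- expand_person_months(bl, ev, horizon_months = 12L,
                             outcome = "primary")
  p1 <- pm[patient_id == 1]
  expect_identical(nrow(p1), 3L)
  expect_identical(p1$event, c(FALSE, FALSE, TRUE))
  p2 <- pm[patient_id == 2]
  expect_identical(nrow(p2), 12L)
  expect_true(p2[month == 11, censor_admin])
  expect_false(any(p2$event))
  p3 <- pm[patient_id == 3]
  expect_identical(nrow(p3), 2L)
  expect_true(p3[month == 1, censor_death])
})

test_that("terminal flags are mutually exclusive and only on the last record", {
  co <- small_pipeline_cohort()
  arms <- assign_treatment_arm(co$baseline, co$fills)
  elig <- apply_eligibility(arms, co$fills, co$events,
                            outcome = "primary")
  pm <- expand_person_months(elig$cohort, co$events, 12L, "primary",
                             co$tv)
  flags <- pm$event + pm$censor_admin + pm$censor_death + pm$censor_ltfu +
    pm$censor_deviation
  expect_true(all(flags <= 1L))
  chk <- pm[, .(consecutive = identical(month, seq_len(.N) - 1L),
                flags_before_last = sum(event[-.N], censor_admin[-.N],
                                        censor_death[-.N],
                                        censor_ltfu[-.N])),
            by = patient_id]
  expect_true(all(chk$consecutive))
  expect_true(all(chk$flags_before_last == 0L))
})

test_that("an outcome event before treatment start is rejected", {
  bl <- make_baseline(1, start = 10L)
  ev <- make_events(1L, "primary", 4L)
  expect_error(expand_person_months(bl, ev, 12L, "primary"), "upstream")
})

test_that("gap rule: a 40-day gap discontinues at coverage end, 25 days does not", {
  bl <- make_baseline(2, arm = c("A", "A"))
  fills <- make_fills(c(1L, 1L, 2L, 2L), c(0L, 70L, 0L, 55L),
                      rep("A", 4))
  dev <- detect_discontinuation(bl, fills, gap_days = 30L,
                                horizon_months = 12L)
  ## 0 + 30 supply ends day 30; next fill day 70: gap 40 >= 30
  expect_identical(dev[patient_id == 1, deviation_day], 30L)
  expect_identical(dev[patient_id == 1, reason], "discontinuation")
  ## gap 25 < 30: coverage restarts at day 55, runs to 85, then the
  ## trailing gap to follow-up end triggers discontinuation at day 85
  expect_identical(dev[patient_id == 2, deviation_day], 85L)
})

test_that("unbroken refill chains never deviate; switches date the deviation", {
  bl <- make_baseline(2, arm = c("A", "A"))
  ## patient 2 keeps an unbroken class-A chain but fills class B at day 45
  ## while still covered: the deviation is the switch, dated at the fill
  fills <- rbind(
    make_fills(rep(1L, 12), seq(0L, 330L, by = 30L), rep("A", 12)),
    make_fills(rep(2L, 13), c(seq(0L, 330L, by = 30L), 45L),
               c(rep("A", 12), "B")))
  dev <- detect_discontinuation(bl, fills, 30L, 12L)
  expect_true(is.na(dev[patient_id == 1, deviation_day]))
  expect_identical(dev[patient_id == 2, deviation_day], 45L)
  expect_identical(dev[patient_id == 2, reason], "switch")
})

test_that("stockpiled overlapping fills extend coverage additively", {
  bl <- make_baseline(1, arm = "A")
  ## fills at 0 and 20 overlap: coverage to 60; next fill day 80 is a
  ## 20-day lapse (< 30), so coverage continues
  fills <- make_fills(rep(1L, 3), c(0L, 20L, 80L), rep("A", 3))
  dev <- detect_discontinuation(bl, fills, 30L, 6L)
  ## coverage ends day 110; follow-up end day 180: trailing gap -> day 110
  expect_identical(dev$deviation_day, 110L)
})

test_that("deviation_at = gap_complete dates the deviation after the gap", {
  bl <- make_baseline(1, arm = "A")
  fills <- make_fills(c(1L, 1L), c(0L, 70L), c("A", "A"))
  dev <- detect_discontinuation(bl, fills, 30L, 12L,
                                deviation_at = "gap_complete")
  expect_identical(dev$deviation_day, 60L)
})

test_that("negative days_supply is rejected", {
  bl <- make_baseline(1)
  fills <- make_fills(1L, 0L, "A", days_supply = -5L)
  expect_error(detect_discontinuation(bl, fills), "days_supply")
})

test_that("ITT censoring returns the table unchanged; PP truncates at deviation", {
  bl <- make_baseline(1, arm = "A")
  ev <- make_events(1L, "primary", 200L)
  pm <- expand_person_months(bl, ev, 12L, "primary")
  dev <- data.table::data.table(patient_id = 1L, deviation_day = 30L,
                                reason = "discontinuation")
  itt <- apply_estimand_censoring(pm, dev, "ITT")
  expect_identical(as.data.frame(itt), as.data.frame(pm))
  pp <- apply_estimand_censoring(pm, dev, "PP")
  expect_identical(nrow(pp), 2L)  # months 0 and 1
  expect_true(pp[month == 1, censor_deviation])
  expect_false(any(pp$event))
})

test_that("an event in the deviation month takes precedence over deviation", {
  bl <- make_baseline(1, arm = "A")
  ev <- make_events(1L, "primary", 40L)   # month 1
  pm <- expand_person_months(bl, ev, 12L, "primary")
  dev <- data.table::data.table(patient_id = 1L, deviation_day = 35L,
                                reason = "discontinuation")  # month 1 too
  pp <- apply_estimand_censoring(pm, dev, "PP")
  expect_true(pp[month == 1, event])
  expect_false(pp[month == 1, censor_deviation])
})

test_that("no deviations makes the PP table identical to ITT", {
  co <- small_pipeline_cohort()
  arms <- eligible_arms(co)
  pm <- expand_person_months(arms, co$events, 12L, "primary")
  none <- data.table::data.table(patient_id = arms$patient_id,
                                 deviation_day = NA_integer_,
                                 reason = NA_character_)
  pp <- apply_estimand_censoring(pm, none, "PP")
  expect_identical(as.data.frame(pp), as.data.frame(pm))
  expect_error(apply_estimand_censoring(pm, none, "per-protocol"),
               "estimand")
})

test_that("PP person-time and events are nested within ITT", {
  co <- small_pipeline_cohort()
  arms <- eligible_arms(co)
  devs <- detect_discontinuation(arms, co$fills, 30L, 12L)
  pm <- expand_person_months(arms, co$events, 12L, "primary", co$tv)
  itt <- apply_estimand_censoring(pm, devs, "ITT")
  pp <- apply_estimand_censoring(pm, devs, "PP")
  expect_lte(nrow(pp), nrow(itt))
  ev_itt <- itt[event == TRUE, paste(patient_id, month)]
  ev_pp <- pp[event == TRUE, paste(patient_id, month)]
  expect_true(all(ev_pp %in% ev_itt))
  ## equality of person-time iff no deviations occurred
  expect_identical(nrow(pp) == nrow(itt), all(is.na(devs$deviation_day)))
})
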