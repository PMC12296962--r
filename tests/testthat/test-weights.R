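test_that("intercept-only propensity model stabilizes to weights of exactly 1", {
  bl <- make_baseline(10, arm = rep(c("A", "B"), 5))
  m <- fit_treatment_model(bl, character(0))
  expect_equal(m$phat, rep(m$pbar, 10))
  w <- stabilized_iptw(m)
  expect_equal(w$iptw_stab, rep(1, 10), tolerance = 1e-12)
})

test_that("saturated one-covariate logit reproduces stratum proportions", {
  ## 80/20 treated at X=1 and 20/80 at X=0 -> fitted p = 0.8 and 0.2
  bl <- make_baseline(200,
                      arm = c(rep("A", 80), rep("B", 20),
                              rep("A", 20), rep("B", 80)))
  bl$x <- c(rep(1, 100), rep(0, 100))
  m <- fit_treatment_model(bl, "x")
  expect_equal(unique(round(m$phat[bl$x == 1], 10)), 0.8)
  expect_equal(unique(round(m$phat[bl$x == 0], 10)), 0.2)
  ## worked stabilized weight: pbar 0.5, phat 0.8, arm A -> 0.625
  w <- stabilized_iptw(m)
  expect_equal(w$iptw_stab[1L], 0.5 / 0.8)
})

test_that("propensity coefficients recover the generating confounder effects", {
  cfg <- sim_scenario_confounding(n_patients = 20000L, seed = 61L)
  co <- generate_cohort(cfg)
  arms <- assign_treatment_arm(co$baseline, co$fills)
  m <- fit_treatment_model(arms, "sev")
  est <- coef(m$fit)[["sev"]]
  se <- sqrt(vcov(m$fit)["sev", "sev"])
  expect_lt(abs(est - 1.5), 3 * se)
})

test_that("stabilization preserves the marginal arm share to numerical precision", {
  ## exact algebraic identity under a saturated propensity model (one
  ## binary covariate -> fitted values are the stratum shares)
  co <- small_pipeline_cohort()
  arms <- assign_treatment_arm(co$baseline, co$fills)
  m <- fit_treatment_model(arms, "frail")
  w <- stabilized_iptw(m)
  armA <- as.numeric(arms$arm == "A")
  expect_lt(abs(weighted.mean(armA, w$iptw_stab) - mean(armA)), 1e-10)
  ## and the weighted pseudo-population is balanced on the covariate
  expect_lt(abs(smd_balance(arms, "frail", w$iptw_stab)$smd), 1e-8)
})

test_that("single-arm input and separation are rejected loudly", {
  bl <- make_baseline(10, arm = rep("A", 10))
  expect_error(fit_treatment_model(bl, character(0)), "both arms")
  bl2 <- make_baseline(40, arm = c(rep("A", 20), rep("B", 20)))
  bl2$px <- c(rep(1, 20), rep(0, 20))  # perfect predictor
  expect_error(fit_treatment_model(bl2, "px"), "separation")
})

test_that("censoring model pair: degenerate with no events, tv-free numerator", {
  co <- small_pipeline_cohort()
  arms <- eligible_arms(co)
  pm <- expand_person_months(arms, co$events, 12L, "primary", co$tv)
  expect_warning(
    mdev <- fit_censoring_model(pm, "deviation", arms,
                                c("frail"), c("thrombocytopenia_t")),
    "degenerate")
  expect_true(mdev$degenerate)
  ipcw0 <- stabilized_ipcw(mdev, pm, arms)
  expect_equal(ipcw0$ipcw_stab_cum, rep(1, nrow(pm)))
  mltfu <- fit_censoring_model(pm, "ltfu", arms, c("frail"),
                               c("thrombocytopenia_t"),
                               time_form = "linear")
  ## structural: numerator never contains time-varying covariates
  expect_false(any(grepl("thrombocytopenia_t",
                         unlist(lapply(mltfu$num_fit,
                                       function(f) names(coef(f)))))))
  expect_true(any(grepl("thrombocytopenia_t",
                        unlist(lapply(mltfu$den_fit,
                                      function(f) names(coef(f)))))))
})

test_that("censoring model recovers a known LTFU log-odds effect", {
  cfg <- sim_config(
    n_patients = 20000L, seed = 71L,
    confounders = confounder_spec("noise", 0.3, 0, 0),
    tv_covariates = tv_covariate_spec("flag_t", 0.3, 0.05, 0.05,
                                      lo_ltfu = 1.0),
    treatment_intercept = 0,
    monthly_discontinuation_prob = c(A = 0, B = 0),
    monthly_switch_prob = c(A = 0, B = 0),
    monthly_ltfu_prob = 0.02, monthly_death_prob = 0,
    pre_treatment_event_prob = 0,
    exclusion_flag_prevalence = c(prior_oac = 0))
  co <- generate_cohort(cfg)
  arms <- assign_treatment_arm(co$baseline, co$fills)
  pm <- expand_person_months(arms, co$events, 12L, "primary", co$tv)
  m <- fit_censoring_model(pm, "ltfu", arms, character(0), "flag_t",
                           time_form = "linear")
  for (a in names(m$den_fit)) {
    est <- coef(m$den_fit[[a]])[["flag_t"]]
    se <- sqrt(vcov(m$den_fit[[a]])["flag_t", "flag_t"])
    expect_lt(abs(est - 1.0), 3 * se)
  }
})

test_that("one-month censoring-weight factor matches hand arithmetic", {
  ## 40 arm-A patients, one month; censoring 10% in the x=1 stratum and
  ## 0% in x=0 -> numerator 0.05 overall, denominator 0.10 for x=1:
  ## weight (1-0.05)/(1-0.10) = 1.0555...
  pm <- data.table::data.table(
    patient_id = 1:40, month = 0L, arm = "A",
    treatment_start_day = 0L, event = FALSE, censor_admin = FALSE,
    censor_death = FALSE,
    censor_ltfu = c(rep(TRUE, 2), rep(FALSE, 18), rep(FALSE, 20)),
    censor_deviation = FALSE,
    x = c(rep(1, 20), rep(0, 20)))
  bl <- make_baseline(40)
  m <- fit_censoring_model(pm, "ltfu", bl, character(0), "x",
                           time_form = "linear")
  ipcw <- stabilized_ipcw(m, pm, bl)
  expect_equal(ipcw[patient_id == 1, ipcw_stab_cum], 0.95 / 0.90,
               tolerance = 1e-6)
  expect_equal(ipcw[patient_id == 40, ipcw_stab_cum], 0.95 / 1.0,
               tolerance = 1e-6)
})

test_that("no censoring at all yields cumulative weights of one", {
  bl <- make_baseline(4, arm = c("A", "A", "B", "B"))
  pm <- expand_person_months(bl, make_events(), 6L, "primary")
  expect_warning(m <- fit_censoring_model(pm, "ltfu", bl), "degenerate")
  ipcw <- stabilized_ipcw(m, pm, bl)
  expect_true(all(ipcw$ipcw_stab_cum == 1))
})

test_that("combine_and_truncate caps at the empirical percentile", {
  ids <- 1:100
  iptw <- data.table::data.table(patient_id = ids,
                                 iptw_stab = c(rep(1, 99), 100))
  ipcw <- data.table::data.table(patient_id = ids, month = 0L,
                                 ipcw_stab_cum = 1)
  ws <- combine_and_truncate(iptw, ipcw, percentile = 95)
  cap <- unname(quantile(c(rep(1, 99), 100), 0.95, type = 7))
  expect_equal(attr(ws, "truncation_cap"), cap)
  expect_equal(max(ws$total_weight), cap)
  ## all-ones input: truncation is the identity with cap 1
  iptw1 <- data.table::data.table(patient_id = ids, iptw_stab = 1)
  ws1 <- combine_and_truncate(iptw1, ipcw, percentile = 99)
  expect_equal(attr(ws1, "truncation_cap"), 1)
  expect_true(all(ws1$total_weight == 1))
  ## variance shrinks, never grows; 95th cap is never above 99th
  ws99 <- combine_and_truncate(iptw, ipcw, percentile = 99)
  expect_lte(var(ws$total_weight), var(ws$total_weight_raw))
  expect_lte(max(ws$total_weight), max(ws99$total_weight))
  expect_error(combine_and_truncate(iptw, ipcw, percentile = 80),
               "percentile")
  ws80 <- combine_and_truncate(iptw, ipcw, truncate_at = 80)
  expect_lte(max(ws80$total_weight), cap)
})

test_that("weighted SMDs fall below 0.1 after IPTW on a confounded cohort", {
  cfg <- sim_scenario_confounding(n_patients = 8000L, seed = 81L)
  co <- generate_cohort(cfg)
  arms <- assign_treatment_arm(co$baseline, co$fills)
  pre <- smd_balance(arms, "sev")
  expect_gt(abs(pre$smd), 0.1)  # confounding is real before weighting
  m <- fit_treatment_model(arms, "sev")
  w <- stabilized_iptw(m)
  post <- smd_balance(arms, "sev", w$iptw_stab)
  expect_lt(abs(post$smd), 0.1)
  expect_lt(abs(mean(w$iptw_stab) - 1), 0.05)
})
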