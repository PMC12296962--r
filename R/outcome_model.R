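#' Weighted pooled logistic discrete-time hazard model
#'
#' Binomial-logit of the monthly event indicator on arm, a function of
#' month, and covariates, with person-month rows weighted by the total
#' (IPTW x IPCW) weight -- the standard marginal-structural-model
#' estimator: an independence working model whose variance is taken from
#' the patient-clustered sandwich estimator. With rare monthly events the
#' exponentiated arm coefficient approximates the hazard ratio of a
#' continuous-time model.
#'
#' @param pm PersonMonth table.
#' @param weights Optional WeightSet from [combine_and_truncate()]
#'   (default: all weights 1).
#' @param cohort Optional PatientBaseline table supplying baseline
#'   covariates.
#' @param covariate_names Baseline covariates to adjust for.
#' @param tv_covariate_names Time-varying covariates (per-protocol
#'   analyses) to adjust for.
#' @param time_form `"indicator"` (categorical month, the default for
#'   12-month horizons), `"spline"` (restricted cubic spline, suited to
#'   36-month horizons), or `"linear"`.
#' @return Object of class `tte_pooled_logistic` with elements `fit`,
#'   `vcov_cluster`, `arm_est`, `arm_se`, `flagged` (TRUE when an arm has
#'   zero events and the HR is unidentifiable), and bookkeeping fields.
#' @export
fit_pooled_logistic <- function(pm, weights = NULL, cohort = NULL,
                                covariate_names = character(0),
                                tv_covariate_names = character(0),
                                time_form = c("indicator", "spline",
                                              "linear")) {
  time_form <- match.arg(time_form)
  check_cols(pm, c("patient_id", "month", "arm", "event"), "pm")
  check_cols(pm, tv_covariate_names, "pm")
  dat <- data.table::as.data.table(pm)
  if (!is.null(weights)) {
    dat <- merge(dat, data.table::as.data.table(weights)[
      , list(patient_id, month, total_weight)],
      by = c("patient_id", "month"), all.x = TRUE, sort = TRUE)
    if (anyNA(dat$total_weight)) {
      tte_stop("weight set does not cover every person-month")
    }
  } else {
    dat[, total_weight := 1]
  }
  if (length(covariate_names)) {
    if (is.null(cohort)) tte_stop("'cohort' needed for baseline covariates")
    check_cols(cohort, c("patient_id", covariate_names), "cohort")
    dat <- merge(dat, data.table::as.data.table(cohort)[
      , c("patient_id", covariate_names), with = FALSE],
      by = "patient_id", sort = TRUE)
  }
  data.table::setorder(dat, patient_id, month)
  dat <- as.data.frame(dat)
  dat$.armA <- as.numeric(dat$arm == "A")

  ev_by_arm <- tapply(dat$event, dat$.armA, sum)
  flagged <- length(ev_by_arm) < 2L || any(ev_by_arm == 0)

  tt <- switch(time_form,
               indicator = "factor(month)",
               spline = "splines::ns(month, df = 4)",
               linear = "month")
  rhs <- paste(c(".armA", tt, covariate_names, tv_covariate_names),
               collapse = " + ")
  fit <- suppressWarnings(
    glm(as.formula(paste("event ~", rhs)), family = quasibinomial(),
        data = dat, weights = total_weight))
  co <- coef(fit)
  named <- co[c(covariate_names, tv_covariate_names)]
  named <- named[!is.na(named)]
  if (length(named) && any(abs(named) > 15)) {
    tte_stop("separation in outcome model (covariate '",
             names(named)[which.max(abs(named))], "')")
  }
  V <- sandwich::vcovCL(fit, cluster = dat$patient_id)
  structure(list(
    fit = fit, vcov_cluster = V,
    arm_est = unname(co[".armA"]),
    arm_se = sqrt(V[".armA", ".armA"]),
    flagged = flagged, time_form = time_form,
    horizon = max(dat$month) + 1L,
    covariate_names = covariate_names,
    tv_covariate_names = tv_covariate_names,
    n_events = sum(dat$event), data = dat),
    class = "tte_pooled_logistic")
}

#' Hazard ratio with cluster-robust confidence interval
#'
#' @param model A [fit_pooled_logistic()] object.
#' @param level Confidence level (default 0.95).
#' @return List `hr`, `ci` (length-2), `flagged`. A model flagged as
#'   unidentifiable (zero events in an arm) propagates `hr = NA` with CI
#'   `(0, Inf)`.
#' @export
hazard_ratio <- function(model, level = 0.95) {
  stopifnot(inherits(model, "tte_pooled_logistic"))
  if (model$flagged) {
    return(list(hr = NA_real_, ci = c(0, Inf), flagged = TRUE))
  }
  z <- qnorm(1 - (1 - level) / 2)
  list(hr = exp(model$arm_est),
       ci = exp(model$arm_est + c(-1, 1) * z * model$arm_se),
       flagged = FALSE)
}

#' Standardized (g-formula) cumulative-incidence curves per arm
#'
#' For each arm, every patient's monthly hazard is predicted with arm set
#' to that value, converted to cumulative incidence
#' `1 - prod(1 - hazard)`, and averaged over patients with stabilized
#' baseline weights. Time-varying covariates in the model, if any, are
#' held at each patient's month-0 value.
#'
#' @param model A [fit_pooled_logistic()] object.
#' @param cohort PatientBaseline table (one row per patient).
#' @param weights Optional per-patient weight table
#'   (`patient_id`, `iptw_stab`); default equal weights.
#' @param horizon Months of cumulative incidence to return; must not
#'   exceed the fitted time range.
#' @return Object of class `tte_risk_curve`: list with `A`, `B`
#'   (cumulative incidence at months `1..horizon`) and `months`.
#' @export
standardized_risk_curves <- function(model, cohort, weights = NULL,
                                     horizon = NULL) {
  stopifnot(inherits(model, "tte_pooled_logistic"))
  horizon <- horizon %||% model$horizon
  if (horizon > model$horizon) {
    tte_stop("'horizon' exceeds the fitted time range (",
             model$horizon, " months)")
  }
  cohort <- data.table::as.data.table(cohort)
  check_cols(cohort, c("patient_id", model$covariate_names), "cohort")
  n <- nrow(cohort)
  grid <- cohort[rep(seq_len(n), each = horizon),
                 c("patient_id", model$covariate_names), with = FALSE]
  grid[, month := rep(seq_len(horizon) - 1L, times = n)]
  if (length(model$tv_covariate_names)) {
    base_tv <- data.table::as.data.table(
      model$data)[month == 0L,
                  c("patient_id", model$tv_covariate_names), with = FALSE]
    grid <- merge(grid, base_tv, by = "patient_id", sort = FALSE)
  }
  griddf <- as.data.frame(grid)
  w <- if (is.null(weights)) rep(1, n) else {
    wt <- merge(cohort[, list(patient_id)],
                data.table::as.data.table(weights), by = "patient_id",
                sort = FALSE)
    wt$iptw_stab
  }
  one_arm <- function(a) {
    griddf$.armA <- as.numeric(a == "A")
    h <- predict(model$fit, newdata = griddf, type = "response")
    hmat <- matrix(h, nrow = n, ncol = horizon, byrow = TRUE)
    surv <- t(apply(1 - hmat, 1L, cumprod))
    if (horizon == 1L) surv <- matrix(surv, nrow = n)
    ci <- 1 - surv
    apply(ci, 2L, function(col) wmean(col, w))
  }
  structure(list(A = one_arm("A"), B = one_arm("B"),
                 months = seq_len(horizon)),
            class = "tte_risk_curve")
}

#' Risk difference at a horizon, with optional bootstrap CI
#'
#' The point estimate is `100 x (CI_A - CI_B)` percentage points at the
#' requested month. A percentile bootstrap CI is produced when a
#' `refit_fun` is supplied: a closure that resamples patients, refits
#' weights and model, and returns a new `tte_risk_curve` (so the CI
#' reflects the whole estimation pipeline, not just the curves).
#'
#' @param curves A [standardized_risk_curves()] object.
#' @param horizon Month at which to evaluate (default: last).
#' @param bootstrap_reps Number of bootstrap replicates (>= 2 when
#'   `refit_fun` is given).
#' @param seed Seed for the bootstrap.
#' @param refit_fun Closure `function()` returning a `tte_risk_curve` for
#'   one bootstrap resample; it should consume the RNG stream.
#' @return List `rd` (percentage points) and `ci` (percentile bootstrap,
#'   `c(NA, NA)` when no `refit_fun` is supplied).
#' @export
risk_difference <- function(curves, horizon = NULL, bootstrap_reps = 0L,
                            seed = 1L, refit_fun = NULL) {
  stopifnot(inherits(curves, "tte_risk_curve"))
  horizon <- horizon %||% max(curves$months)
  k <- match(horizon, curves$months)
  if (is.na(k)) tte_stop("'horizon' outside the curve's time range")
  rd <- 100 * (curves$A[k] - curves$B[k])
  ci <- c(NA_real_, NA_real_)
  if (!is.null(refit_fun)) {
    if (bootstrap_reps < 2) tte_stop("'bootstrap_reps' must be >= 2")
    set.seed(seed)
    rds <- vapply(seq_len(bootstrap_reps), function(r) {
      cv <- refit_fun()
      100 * (cv$A[k] - cv$B[k])
    }, numeric(1))
    ci <- unname(quantile(rds, c(0.025, 0.975), type = 7))
  }
  list(rd = rd, ci = ci)
}
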