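#' Fit the propensity (treatment) model
#'
#' Main-effects binomial-logit model of arm A membership on baseline
#' covariates, fit on one row per patient. Complete separation is
#' surfaced as an error naming the most extreme covariate rather than
#' silently producing degenerate weights.
#'
#' @param cohort PatientBaseline table with `arm` in `{"A","B"}` and
#'   complete covariates (run [impute_missing()] first if needed).
#' @param covariate_names Baseline covariate columns; empty for an
#'   intercept-only model.
#' @return Object of class `tte_treatment_model` exposing the glm `fit`,
#'   per-patient fitted probability `phat`, and marginal arm-A share
#'   `pbar`.
#' @export
fit_treatment_model <- function(cohort, covariate_names = character(0)) {
  check_cols(cohort, c("patient_id", "arm"), "cohort")
  check_cols(cohort, covariate_names, "cohort")
  cohort <- data.table::as.data.table(cohort)
  if (!all(c("A", "B") %in% cohort$arm)) {
    tte_stop("both arms must be present to fit a treatment model")
  }
  dat <- as.data.frame(cohort[, c("arm", covariate_names), with = FALSE])
  dat$.treat <- as.numeric(dat$arm == "A")
  rhs <- if (length(covariate_names)) {
    paste(covariate_names, collapse = " + ")
  } else "1"
  ## tight convergence: the stabilization identity (weighted arm share =
  ## unweighted share) holds exactly only at the score equations' root
  ## separation is surfaced as an error below, not left as a glm warning
  fit <- suppressWarnings(
    glm(as.formula(paste(".treat ~", rhs)), family = binomial(),
        data = dat,
        control = stats::glm.control(epsilon = 1e-14, maxit = 100)))
  phat <- unname(fit$fitted.values)
  if (any(phat < 1e-10 | phat > 1 - 1e-10)) {
    co <- coef(fit)[-1L]
    worst <- if (length(co)) names(co)[which.max(abs(co))] else "(intercept)"
    tte_stop("complete separation in treatment model (covariate '",
             worst, "'); positivity violated")
  }
  structure(list(fit = fit, phat = phat, pbar = mean(dat$.treat),
                 covariate_names = covariate_names,
                 patient_id = cohort$patient_id),
            class = "tte_treatment_model")
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Arm A patients receive `P(A) / phat_i`, arm B patients
#' `P(B) / (1 - phat_i)`, with `P(.)` the marginal arm share -- so an
#' intercept-only model yields weights of exactly 1, and the weighted arm
#' share always equals the unweighted one. The weight is constant over a
#' patient's person-months.
#'
#' @param model A [fit_treatment_model()] object.
#' @param cohort Optional cohort to score (defaults to the fitting data).
#' @return data.table `patient_id`, `iptw_stab`.
#' @export
stabilized_iptw <- function(model, cohort = NULL) {
  stopifnot(inherits(model, "tte_treatment_model"))
  if (is.null(cohort)) {
    ids <- model$patient_id
    phat <- model$phat
    treat <- model$fit$model$.treat
  } else {
    cohort <- data.table::as.data.table(cohort)
    check_cols(cohort, c("patient_id", "arm", model$covariate_names),
               "cohort")
    ids <- cohort$patient_id
    phat <- unname(predict(model$fit, newdata = as.data.frame(cohort),
                           type = "response"))
    treat <- as.numeric(cohort$arm == "A")
  }
  if (any(phat < 1e-10 | phat > 1 - 1e-10)) {
    tte_stop("fitted treatment probability numerically 0 or 1; ",
             "positivity violated")
  }
  w <- ifelse(treat == 1, model$pbar / phat, (1 - model$pbar) / (1 - phat))
  data.table::data.table(patient_id = ids, iptw_stab = w)
}

#' Fit a cause-specific censoring-hazard model pair
#'
#' Pooled binomial-logit of the monthly cause-specific censoring
#' indicator over all at-risk person-months, stratified by treatment arm.
#' The denominator model uses the month index, baseline covariates, and
#' time-varying covariates; the stabilizing numerator model uses the
#' month index and baseline covariates only (never time-varying ones).
#' With zero censoring events of the cause, both models degenerate to
#' probability 0 and the resulting weights are 1 (a warning is raised).
#'
#' @param pm PersonMonth table.
#' @param cause `"ltfu"` or `"deviation"`.
#' @param cohort PatientBaseline table supplying baseline covariates.
#' @param baseline_covariates,tv_covariates Covariate column names.
#' @param time_form `"indicator"` (factor month) or `"linear"`.
#' @return Object of class `tte_censoring_model`.
#' @export
fit_censoring_model <- function(pm, cause = c("ltfu", "deviation"), cohort,
                                baseline_covariates = character(0),
                                tv_covariates = character(0),
                                time_form = c("indicator", "linear")) {
  cause <- match.arg(cause)
  time_form <- match.arg(time_form)
  ind_col <- paste0("censor_", cause)
  check_cols(pm, c("patient_id", "month", ind_col), "pm")
  check_cols(pm, tv_covariates, "pm")
  check_cols(cohort, c("patient_id", baseline_covariates), "cohort")
  pm <- data.table::as.data.table(pm)
  dat <- merge(pm,
               data.table::as.data.table(cohort)[
                 , c("patient_id", baseline_covariates), with = FALSE],
               by = "patient_id", sort = TRUE)
  dat <- as.data.frame(dat)
  dat$.cens <- as.numeric(dat[[ind_col]])

  out <- list(cause = cause, degenerate = FALSE,
              baseline_covariates = baseline_covariates,
              tv_covariates = tv_covariates, time_form = time_form,
              numerator_terms = c("month", baseline_covariates))
  if (sum(dat$.cens) == 0) {
    warning("no '", cause, "' censoring events; weights degenerate to 1")
    out$degenerate <- TRUE
    class(out) <- "tte_censoring_model"
    return(out)
  }
  ## Models are stratified by treatment arm (the full arm-interaction
  ## form): censoring hazards and their covariate associations are allowed
  ## to differ between arms, and arm is retained in the marginal
  ## structural outcome model, so stratified stabilization stays valid.
  tt <- if (time_form == "indicator") "factor(month)" else "month"
  den_rhs <- paste(c(tt, baseline_covariates, tv_covariates),
                   collapse = " + ")
  num_rhs <- paste(c(tt, baseline_covariates), collapse = " + ")
  out$den_fit <- list(); out$num_fit <- list()
  for (a in unique(dat$arm)) {
    sub <- dat[dat$arm == a, , drop = FALSE]
    if (sum(sub$.cens) == 0) next  # degenerate in this arm: hazard 0
    out$den_fit[[a]] <- suppressWarnings(
      glm(as.formula(paste(".cens ~", den_rhs)), family = binomial(),
          data = sub))
    out$num_fit[[a]] <- suppressWarnings(
      glm(as.formula(paste(".cens ~", num_rhs)), family = binomial(),
          data = sub))
  }
  class(out) <- "tte_censoring_model"
  out
}

#' Stabilized inverse-probability-of-censoring weights
#'
#' The month-k weight is the cumulative product over months `j <= k` of
#' `[1 - p_num(j)] / [1 - p_den(j)]`, where the numerator and denominator
#' are the stabilizing and full censoring-hazard models. Several models
#' (e.g. loss to follow-up plus, for per-protocol, treatment deviation)
#' multiply into one product.
#'
#' @param models A `tte_censoring_model` or list of them.
#' @param pm PersonMonth table.
#' @param cohort PatientBaseline table for baseline covariates.
#' @return data.table `patient_id`, `month`, `ipcw_stab_cum`.
#' @export
stabilized_ipcw <- function(models, pm, cohort) {
  if (inherits(models, "tte_censoring_model")) models <- list(models)
  pm <- data.table::as.data.table(pm)
  data.table::setorder(pm, patient_id, month)
  factor_total <- rep(1, nrow(pm))
  for (mod in models) {
    stopifnot(inherits(mod, "tte_censoring_model"))
    if (mod$degenerate) next
    dat <- merge(pm,
                 data.table::as.data.table(cohort)[
                   , c("patient_id", mod$baseline_covariates), with = FALSE],
                 by = "patient_id", sort = TRUE)
    data.table::setorder(dat, patient_id, month)  # align with pm rows
    dat <- as.data.frame(dat)
    p_den <- numeric(nrow(dat))
    p_num <- numeric(nrow(dat))
    for (a in names(mod$den_fit)) {
      rows <- dat$arm == a
      p_den[rows] <- unname(predict(mod$den_fit[[a]],
                                    newdata = dat[rows, , drop = FALSE],
                                    type = "response"))
      p_num[rows] <- unname(predict(mod$num_fit[[a]],
                                    newdata = dat[rows, , drop = FALSE],
                                    type = "response"))
    }
    surv_den <- 1 - p_den
    if (any(surv_den <= 1e-12)) {
      tte_stop("censoring-model denominator probability reaches 1; ",
               "positivity violated")
    }
    factor_total <- factor_total * (1 - p_num) / surv_den
  }
  out <- pm[, list(patient_id, month)]
  out[, ipcw_stab_cum := factor_total]
  out[, ipcw_stab_cum := cumprod(ipcw_stab_cum), by = patient_id]
  out[]
}

#' Combine and truncate weights
#'
#' Total per person-month weight is the product of the patient's
#' stabilized treatment weight and the cumulative stabilized censoring
#' weight; totals above the chosen empirical percentile (linear
#' interpolation over all person-months) are capped at it.
#'
#' @param iptw data.table from [stabilized_iptw()].
#' @param ipcw data.table from [stabilized_ipcw()].
#' @param percentile `"none"`, `95`, or `99`.
#' @param truncate_at Optional explicit percentile in (50, 100),
#'   overriding `percentile`.
#' @return WeightSet data.table (`patient_id`, `month`, `iptw_stab`,
#'   `ipcw_stab_cum`, `total_weight_raw`, `total_weight`) with attributes
#'   `truncation_cap` and `truncation_percentile`.
#' @export
combine_and_truncate <- function(iptw, ipcw, percentile = 99,
                                 truncate_at = NULL) {
  if (!is.null(truncate_at)) {
    if (truncate_at <= 50 || truncate_at >= 100) {
      tte_stop("'truncate_at' must lie in (50, 100)")
    }
    pct <- truncate_at
  } else if (identical(percentile, "none")) {
    pct <- NA_real_
  } else if (percentile %in% c(95, 99)) {
    pct <- as.numeric(percentile)
  } else {
    tte_stop("'percentile' must be 'none', 95, or 99 ",
             "(or pass 'truncate_at' explicitly)")
  }
  ws <- merge(data.table::as.data.table(ipcw),
              data.table::as.data.table(iptw), by = "patient_id",
              sort = TRUE)
  ws[, total_weight_raw := iptw_stab * ipcw_stab_cum]
  if (is.na(pct)) {
    cap <- Inf
    ws[, total_weight := total_weight_raw]
  } else {
    cap <- unname(quantile(ws$total_weight_raw, pct / 100, type = 7))
    ws[, total_weight := pmin(total_weight_raw, cap)]
  }
  data.table::setorder(ws, patient_id, month)
  data.table::setattr(ws, "truncation_cap", cap)
  data.table::setattr(ws, "truncation_percentile", pct)
  ws[]
}

#' Weighted standardized mean differences across arms
#'
#' The operational balance check for the weighting stage: after correct
#' stabilized IPTW, every modeled covariate's absolute SMD should fall
#' below 0.1.
#'
#' @param cohort PatientBaseline table with `arm`.
#' @param covariate_names Covariates to compare (binary or continuous).
#' @param weights Per-patient weights aligned with `cohort` rows
#'   (default 1 = unweighted).
#' @return data.table `covariate`, `smd`.
#' @export
smd_balance <- function(cohort, covariate_names, weights = NULL) {
  cohort <- data.table::as.data.table(cohort)
  check_cols(cohort, c("arm", covariate_names), "cohort")
  w <- weights %||% rep(1, nrow(cohort))
  a <- cohort$arm == "A"
  out <- lapply(covariate_names, function(v) {
    x <- as.numeric(cohort[[v]])
    m1 <- wmean(x[a], w[a]); m0 <- wmean(x[!a], w[!a])
    s2 <- (wvar(x[a], w[a]) + wvar(x[!a], w[!a])) / 2
    data.table::data.table(covariate = v,
                           smd = (m1 - m0) / sqrt(max(s2, 1e-12)))
  })
  data.table::rbindlist(out)
}

#' Summary diagnostics for a weight set
#'
#' @param ws WeightSet from [combine_and_truncate()].
#' @return data.table with mean, SD, max, and the truncation cap.
#' @export
weight_diagnostics <- function(ws) {
  data.table::data.table(
    mean_weight = mean(ws$total_weight),
    sd_weight = sd(ws$total_weight),
    max_weight = max(ws$total_weight),
    mean_iptw = mean(ws$iptw_stab),
    truncation_cap = attr(ws, "truncation_cap"))
}
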