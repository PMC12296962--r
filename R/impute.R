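## columns never imputed and never used as FCS predictors of themselves
.protected_cols <- c("patient_id", "index_day", "arm", "treatment_start_day")

#' Multiple imputation by chained equations
#'
#' Fully conditional specification: each incomplete covariate is regressed
#' on all other covariates and re-imputed in turn for a fixed number of
#' sweeps. Binary variables use logistic regression with a posterior draw
#' of the coefficients; factors with more than two levels use multinomial
#' regression draws (via \pkg{nnet}); continuous variables use predictive
#' mean matching (type-1, `pmm_k` donor candidates), so every imputed
#' continuous value equals some observed value. Observed cells are never
#' altered. Identifier, arm, and date fields must be complete.
#'
#' @param patients PatientBaseline table, possibly with `NA` covariates.
#' @param n_imputations Number of completed tables to return.
#' @param max_iter FCS sweeps per imputation.
#' @param seed Seed; results are deterministic given it.
#' @param pmm_k Number of donor candidates for predictive mean matching.
#' @return A list of `n_imputations` completed `data.table`s.
#' @export
impute_missing <- function(patients, n_imputations = 1L, max_iter = 5L,
                           seed = 1L, pmm_k = 5L) {
  dt <- data.table::as.data.table(patients)
  prot <- intersect(.protected_cols, names(dt))
  if (anyNA(dt[, ..prot])) {
    tte_stop("missing values in protected fields (id/arm/dates) are not allowed")
  }
  covars <- setdiff(names(dt), prot)
  n_na <- vapply(dt[, ..covars], function(x) sum(is.na(x)), integer(1))
  all_na <- covars[n_na == nrow(dt)]
  if (length(all_na)) {
    tte_stop("variable '", all_na[[1L]], "' is missing for all patients")
  }
  targets <- covars[n_na > 0L]
  if (!length(targets)) {
    return(lapply(seq_len(n_imputations), function(m) data.table::copy(dt)))
  }

  miss_idx <- lapply(dt[, ..targets], function(x) which(is.na(x)))
  names(miss_idx) <- targets

  lapply(seq_len(n_imputations), function(m) {
    set.seed(seed + 1009L * m)
    work <- data.table::copy(dt)
    ## initialize missing cells by sampling observed values
    for (v in targets) {
      obs <- work[[v]][!is.na(work[[v]])]
      data.table::set(work, i = miss_idx[[v]], j = v,
                      value = sample(obs, length(miss_idx[[v]]),
                                     replace = TRUE))
    }
    for (iter in seq_len(max_iter)) {
      for (v in targets) {
        data.table::set(work, j = v,
                        value = impute_one(work, v, covars, miss_idx[[v]],
                                           pmm_k))
      }
    }
    work[]
  })
}

#' One FCS update of a single variable
#' @noRd
impute_one <- function(work, v, covars, mis, pmm_k) {
  y <- work[[v]]
  preds <- setdiff(covars, v)
  pd <- as.data.frame(work[, ..preds])
  for (j in names(pd)) {
    if (is.character(pd[[j]])) pd[[j]] <- factor(pd[[j]])
    if (is.logical(pd[[j]])) pd[[j]] <- as.numeric(pd[[j]])
    ## constant predictors carry no information and break the contrasts
    if (length(unique(pd[[j]][!is.na(pd[[j]])])) < 2L) pd[[j]] <- NULL
  }
  if (!ncol(pd)) pd <- data.frame(.const = rep(1, nrow(work)))
  X <- model.matrix(~ ., data = pd)
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  obs <- setdiff(seq_along(y), mis)

  is_binary <- is.logical(y) ||
    (is.numeric(y) && all(y[obs] %in% c(0, 1))) ||
    ((is.character(y) || is.factor(y)) && length(unique(y[obs])) == 2L)
  if (is_binary) {
    lev <- if (is.logical(y)) c(FALSE, TRUE)
           else sort(unique(y[obs]))
    yy <- as.numeric(y[obs] == lev[[2L]])
    fit <- glm.fit2(X[obs, , drop = FALSE], yy, binomial())
    beta <- draw_beta(fit)
    p <- plogis(drop(X[mis, , drop = FALSE] %*% beta))
    draw <- rbinom(length(mis), 1L, p) == 1L
    y[mis] <- if (is.logical(y)) draw else lev[as.integer(draw) + 1L]
  } else if (is.numeric(y)) {
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    keep <- !is.na(fit$coefficients)
    Xk <- X[, keep, drop = FALSE]
    bhat <- fit$coefficients[keep]
    res <- fit$residuals
    df <- max(length(obs) - sum(keep), 1L)
    sigma2 <- sum(res^2) / rchisq(1L, df)
    XtX <- crossprod(Xk[obs, , drop = FALSE])
    V <- sigma2 * solve(XtX + diag(1e-8, ncol(XtX)))
    beta <- bhat + drop(chol_of(V) %*% rnorm(length(bhat)))
    yhat_obs <- drop(Xk[obs, , drop = FALSE] %*% bhat)
    yhat_mis <- drop(Xk[mis, , drop = FALSE] %*% beta)
    ## type-1 PMM: match drawn predictions to observed-fit predictions
    donors <- vapply(yhat_mis, function(pt) {
      k <- min(pmm_k, length(yhat_obs))
      cand <- order(abs(yhat_obs - pt))[seq_len(k)]
      obs[sample(cand, 1L)]
    }, integer(1))
    y[mis] <- y[donors]
  } else {
    if (!requireNamespace("nnet", quietly = TRUE)) {
      tte_stop("package 'nnet' is needed to impute factors with >2 levels")
    }
    yy <- factor(y[obs])
    tr <- as.data.frame(X[obs, -1L, drop = FALSE])
    te <- as.data.frame(X[mis, -1L, drop = FALSE])
    fit <- nnet::multinom(.y ~ ., data = data.frame(.y = yy, tr),
                          trace = FALSE)
    p <- predict(fit, newdata = te, type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = length(mis))
    lev <- levels(yy)
    y[mis] <- vapply(seq_along(mis), function(i) {
      lev[sample(length(lev), 1L, prob = p[i, ])]
    }, character(1))
  }
  y
}

#' Logistic fit returning coefficients and unscaled covariance
#' @noRd
glm.fit2 <- function(X, y, family) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = family))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  V <- solve(XtWX + diag(1e-8, ncol(XtWX)))
  list(coefficients = co, V = V)
}

#' @noRd
draw_beta <- function(fit) {
  fit$coefficients + drop(chol_of(fit$V) %*% rnorm(length(fit$coefficients)))
}

#' Lower-triangular factor, tolerant of near-singular covariance
#' @noRd
chol_of <- function(V) {
  out <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(out)) out <- t(chol(V + diag(1e-6 * max(diag(V)), ncol(V))))
  out
}
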