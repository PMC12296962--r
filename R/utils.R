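`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent error class
#' @noRd
tte_stop <- function(..., class = "claimstte_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

#' Check that a probability-like scalar/vector lies in [0, 1]
#' @noRd
check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    tte_stop("'", name, "' must be numeric in [0, 1]")
  }
  invisible(x)
}

#' Check that required columns are present, naming the first absent one
#' @noRd
check_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    tte_stop("required field '", missing[[1L]], "' absent from ", what)
  }
  invisible(df)
}

#' Per-patient substream seed: patient i's stream is a pure function of the
#' root seed and i, so growing n_patients never reshuffles earlier patients.
#' @noRd
patient_seed <- function(root_seed, i) {
  (abs(as.numeric(root_seed)) + 11 + as.numeric(i) * 7919) %% 2147483647
}

#' Weighted mean / variance helpers used in balance diagnostics
#' @noRd
wmean <- function(x, w) sum(w * x) / sum(w)

#' @noRd
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}
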