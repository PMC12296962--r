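#' Write / read a cohort as CSV tables
#'
#' The four module tables (`baseline`, `fills`, `events`, `tv`) are
#' written as plain CSV files with their documented column names, one
#' file per table.
#'
#' @param cohort A `tte_cohort` list.
#' @param dir Directory (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   a `tte_cohort` list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("baseline", "fills", "events", "tv")) {
    if (!is.null(cohort[[nm]])) {
      data.table::fwrite(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  need <- c("baseline", "fills", "events")
  out <- list()
  for (nm in c(need, "tv")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path)) {
      out[[nm]] <- data.table::fread(path)
    } else if (nm %in% need) {
      tte_stop("missing input table '", nm, ".csv' in ", dir)
    }
  }
  structure(out, class = "tte_cohort")
}

#' Write pipeline results to CSV files
#'
#' Emits `estimates.csv`, one `curves_<estimand>_<outcome>.csv` per
#' combination, `attrition_<outcome>.csv`, and `weight_diagnostics.csv`.
#'
#' @param results A `tte_results` from [run_analysis()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(results$estimates, file.path(dir, "estimates.csv"))
  for (key in names(results$curves)) {
    cv <- results$curves[[key]]
    data.table::fwrite(
      data.table::data.table(month = cv$months, cuminc_A = cv$A,
                             cuminc_B = cv$B),
      file.path(dir, paste0("curves_", gsub("[^A-Za-z0-9_.-]", "_", key),
                            ".csv")))
  }
  for (oc in names(results$attrition)) {
    data.table::fwrite(results$attrition[[oc]],
                       file.path(dir, paste0("attrition_", oc, ".csv")))
  }
  if (length(results$weight_diagnostics)) {
    wd <- data.table::rbindlist(results$weight_diagnostics,
                                idcol = "analysis")
    data.table::fwrite(wd, file.path(dir, "weight_diagnostics.csv"))
  }
  invisible(dir)
}
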