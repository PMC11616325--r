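#' Read a raw ASL series table
#'
#' Reads the long-format CSV schema used for raw ROI signals: columns
#' `subject_id`, `protocol` (`standard`/`bcsfb`), `roi`, `ti_ms`,
#' optional `acquisition`, `condition` (`selective`/`nonselective`),
#' `repetition`, `signal`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_asl_series <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "protocol", "ti_ms", "condition",
                "repetition", "signal")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols))
    abort(paste("ASL series file lacks columns:",
                paste(missing_cols, collapse = ", ")))
  out
}

#' Write a raw ASL series table
#'
#' @param data ASL series tibble (see [read_asl_series()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_asl_series <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Export subject records as CSV
#'
#' Writes quantified subject records (without list-columns) to CSV.
#'
#' @param records Records tibble from [quantify_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  flat <- records[, !vapply(records, is.list, logical(1))]
  readr::write_csv(flat, path)
  invisible(path)
}

#' Export a kinetic fit as JSON
#'
#' @param fit A `kinetic_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    model = fit$model,
    params = as.list(fit$params),
    std_error = as.list(fit$std_error),
    free = fit$free,
    residual_norm = fit$residual_norm,
    converged = fit$converged,
    n_iter = fit$n_iter,
    data = fit$data
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
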