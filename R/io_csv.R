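required_summary_cols <- c("hcf", "sd", "deaths")
required_daily_cols <- c("cow", "grazing_day", "daily_msal_mg")

check_schema <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Run-summary and daily-intake CSV interchange
#'
#' Comma-separated UTF-8 files with one header row. Readers validate the
#' required columns (`hcf`, `sd`, `deaths` for run summaries; `cow`,
#' `grazing_day`, `daily_msal_mg` for daily records) and preserve any extra
#' columns, so externally produced end-of-simulation tables with a superset
#' of columns load unchanged.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_run_summaries <- function(df, path) {
  check_schema(df, required_summary_cols, "run-summary", path)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_summaries
#' @export
read_run_summaries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, required_summary_cols, "run-summary", path)
}

#' @rdname write_run_summaries
#' @export
write_daily_records <- function(df, path) {
  check_schema(df, required_daily_cols, "daily-intake", path)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_summaries
#' @export
read_daily_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, required_daily_cols, "daily-intake", path)
}
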