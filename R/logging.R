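# Machine-parsable log lines shared by the correction and tuning reports:
# ISO-8601 timestamp, record kind, then tab-separated key=value details.

format_log_lines <- function(records) {
  vapply(records, function(r) {
    details <- paste(sprintf("%s=%s", names(r$details),
                             as.character(r$details)), collapse = "\t")
    paste(format(r$timestamp, "%Y-%m-%dT%H:%M:%S%z"), r$kind, details,
          sep = "\t")
  }, character(1))
}

write_log_records <- function(records, path, append = FALSE) {
  con <- file(path, open = if (append) "ab" else "wb")
  on.exit(close(con))
  lines <- format_log_lines(records)
  if (length(lines))
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(length(lines))
}

#' Write a correction report to a log file
#'
#' One line per record: ISO timestamp, record kind, tab-separated
#' `key=value` detail fields.
#'
#' @param report a `correction_report`
#' @param path log file path
#' @param append append to an existing log instead of overwriting
#' @return number of lines written, invisibly
#' @export
write_correction_log <- function(report, path, append = FALSE) {
  invisible(write_log_records(report$records, path, append))
}

#' Write a tuning report to a log file
#'
#' Same line format as [write_correction_log()].
#'
#' @param report a `tuning_report`
#' @param path log file path
#' @param append append to an existing log instead of overwriting
#' @return number of lines written, invisibly
#' @export
write_tuning_log <- function(report, path, append = FALSE) {
  invisible(write_log_records(report$records, path, append))
}
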