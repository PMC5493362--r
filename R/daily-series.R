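#' Daily exposure / admissions series
#'
#' A date-indexed data frame of daily pollutant concentrations, weather and
#' observed admission counts.  Recognised columns: `date` (ISO-8601),
#' `pm10`, `o3`, `so2` (ug/m3), `temp` (ambient C), `rh` (relative
#' humidity, percent), `temp_apparent` (C) and `admissions` (non-negative
#' integer count).  Either `temp_apparent` or the pair `temp` + `rh` must
#' be present; missing values are `NA`.
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame with class `daily_series`.
#' @export
daily_series <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"date" %in% names(df))
    stop("a daily series needs a 'date' column", call. = FALSE)
  df$date <- as.Date(df$date)
  if (anyNA(df$date))
    stop("unparseable dates (expected ISO-8601, e.g. 2007-01-31)",
         call. = FALSE)
  problems <- character(0)
  chk_num <- function(col) {
    if (col %in% names(df)) {
      bad <- which(!is.na(df[[col]]) & !is.finite(suppressWarnings(
        as.numeric(df[[col]]))))
      if (length(bad))
        problems <<- c(problems, paste0("non-numeric '", col, "' in row(s) ",
                                        paste(bad, collapse = ", ")))
      df[[col]] <<- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  for (col in c("pm10", "o3", "so2", "temp", "rh", "temp_apparent",
                "admissions")) chk_num(col)
  for (col in c("pm10", "o3", "so2")) {
    if (col %in% names(df)) {
      bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
      if (length(bad))
        problems <- c(problems, paste0("negative '", col, "' in row(s) ",
                                       paste(bad, collapse = ", ")))
    }
  }
  if ("rh" %in% names(df)) {
    bad <- which(!is.na(df$rh) & (df$rh < 0 | df$rh > 100))
    if (length(bad))
      problems <- c(problems, paste0("'rh' outside [0, 100] in row(s) ",
                                     paste(bad, collapse = ", ")))
  }
  if ("admissions" %in% names(df)) {
    bad <- which(!is.na(df$admissions) &
                   (df$admissions < 0 | df$admissions %% 1 != 0))
    if (length(bad))
      problems <- c(problems,
                    paste0("'admissions' must be a non-negative integer ",
                           "count; bad row(s) ", paste(bad, collapse = ", ")))
  }
  if (!("temp_apparent" %in% names(df)) &&
      !all(c("temp", "rh") %in% names(df)))
    stop("a daily series needs 'temp_apparent' or both 'temp' and 'rh'",
         call. = FALSE)
  if (length(problems))
    stop("malformed daily series:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  class(df) <- c("daily_series", "data.frame")
  df
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d day(s), %s to %s\n", nrow(x),
              min(x$date), max(x$date)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write a daily series as CSV
#'
#' Comma-delimited UTF-8 with a header row, ISO-8601 dates and empty fields
#' for missing values.  Malformed rows are reported with their line
#' numbers (header = line 1).
#'
#' @param path CSV file path.
#' @return `read_daily_csv()` returns a [daily_series()];
#'   `write_daily_csv()` returns `path` invisibly.
#' @export
read_daily_csv <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  tryCatch(daily_series(df), error = function(e) {
    # translate data-frame row indices into file line numbers (header +1)
    msg <- gsub("row\\(s\\) ([0-9, ]+)", "row(s) \\1", conditionMessage(e))
    stop("while reading ", path, " (add 1 to row numbers for file lines): ",
         msg, call. = FALSE)
  })
}

#' @rdname read_daily_csv
#' @param series A [daily_series()] or compatible data frame.
#' @export
write_daily_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
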