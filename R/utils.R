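# Internal helpers: date/month arithmetic and presentation rounding.

#' Round half away from zero
#'
#' Presentation-layer rounding used for all printed percentages and rates.
#' Base [round()] rounds half to even; published epidemiological tables round
#' half up, so `round_half_up(36.05, 1)` is 36.1, not 36.0.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Calendar month index (months since 0000-01): differences give calendar-month
# offsets irrespective of day of month.
month_index <- function(date) {
  lt <- as.POSIXlt(date)
  (lt$year + 1900L) * 12L + lt$mon
}

# Calendar-month difference: later minus earlier (positive when `a` precedes `b`).
month_diff <- function(b, a) month_index(b) - month_index(a)

# Number of days in the month containing the (year, month0) pair; vectorized.
days_in_month <- function(year, mon0) {
  nxt_y <- ifelse(mon0 == 11L, year + 1L, year)
  nxt_m <- ifelse(mon0 == 11L, 0L, mon0 + 1L)
  first <- as.Date(sprintf("%04d-%02d-01", year, mon0 + 1L))
  nxt <- as.Date(sprintf("%04d-%02d-01", nxt_y, nxt_m + 1L))
  as.integer(nxt - first)
}

# Parse ISO-8601 dates strictly; `what`/`file` feed error diagnostics.
parse_iso_date <- function(x, what = "date", file = NULL) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable %s %s at row %d%s (expected ISO-8601 YYYY-MM-DD)",
                 what, dQuote(as.character(x)[bad[1L]]), bad[1L],
                 if (is.null(file)) "" else paste0(" of ", file)),
         call. = FALSE)
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, file = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 file, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
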