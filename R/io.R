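# Readers and writers for the three linked record collections. All files are
# comma-delimited with a header row and ISO-8601 dates; the hospital file
# carries 22 blank-padded diagnosis fields (diag1..diag22).

#' Read and write maternity, hospital and registry files
#'
#' `read_maternities()` expects columns `woman_id`, `maternity_id`,
#' `delivery_date`, `gestation_weeks`. `read_hospital()` expects `woman_id`,
#' `record_id`, `admission_date`, `diag1` ... `diag22` (trailing blank
#' fields may be empty). `read_registry()` expects `woman_id`,
#' `registry_id`, `diagnosis_date`, `group`, `first_notification_date`,
#' where `first_notification_date` is the earliest registry notification of
#' that clinical group for that woman within the lookback horizon and is
#' never after `diagnosis_date`.
#'
#' Files failing these contracts (missing columns, unparseable dates, unknown
#' group labels, notification after diagnosis) are rejected with a message
#' naming the file and row.
#'
#' @param path file path.
#' @return a validated data.frame with `Date` date columns.
#' @name record_io
NULL

#' @rdname record_io
#' @export
read_maternities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot_cols(df, c("woman_id", "maternity_id", "delivery_date",
                       "gestation_weeks"), path)
  df$delivery_date <- parse_iso_date(df$delivery_date, "delivery_date", path)
  df$gestation_weeks <- as.integer(df$gestation_weeks)
  df
}

#' @rdname record_io
#' @export
read_hospital <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot_cols(df, c("woman_id", "record_id", "admission_date", "diag1"), path)
  df$admission_date <- parse_iso_date(df$admission_date, "admission_date", path)
  dcols <- grep("^diag[0-9]+$", names(df), value = TRUE)
  if (length(dcols) > 22L) {
    stop(sprintf("%s has %d diagnosis fields; at most 22 are supported",
                 path, length(dcols)), call. = FALSE)
  }
  df
}

#' @rdname record_io
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot_cols(df, c("woman_id", "registry_id", "diagnosis_date", "group",
                       "first_notification_date"), path)
  df$diagnosis_date <- parse_iso_date(df$diagnosis_date, "diagnosis_date", path)
  df$first_notification_date <-
    parse_iso_date(df$first_notification_date, "first_notification_date", path)
  bad <- which(!df$group %in% clinical_groups())
  if (length(bad) > 0L) {
    stop(sprintf("unknown clinical group %s at row %d of %s",
                 dQuote(df$group[bad[1L]]), bad[1L], path), call. = FALSE)
  }
  late <- which(df$first_notification_date > df$diagnosis_date)
  if (length(late) > 0L) {
    stop(sprintf("first_notification_date after diagnosis_date at row %d of %s",
                 late[1L], path), call. = FALSE)
  }
  df
}

#' @rdname record_io
#' @param df data.frame to write.
#' @export
write_maternities <- function(df, path) {
  out <- df[, c("woman_id", "maternity_id", "delivery_date", "gestation_weeks")]
  out$delivery_date <- format(as.Date(out$delivery_date))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname record_io
#' @export
write_hospital <- function(df, path) {
  dcols <- grep("^diag[0-9]+$", names(df), value = TRUE)
  out <- data.frame(woman_id = df$woman_id, record_id = df$record_id,
                    admission_date = format(as.Date(df$admission_date)),
                    stringsAsFactors = FALSE)
  for (j in 1:22) {
    col <- paste0("diag", j)
    out[[col]] <- if (col %in% dcols) {
      v <- df[[col]]
      ifelse(is.na(v), "", v)
    } else ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname record_io
#' @export
write_registry <- function(df, path) {
  out <- df[, c("woman_id", "registry_id", "diagnosis_date", "group",
                "first_notification_date")]
  out$diagnosis_date <- format(as.Date(out$diagnosis_date))
  out$first_notification_date <- format(as.Date(out$first_notification_date))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
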