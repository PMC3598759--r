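#' Build pregnancy-associated exposure windows
#'
#' For each maternity the exposure window runs from conception, approximated
#' as `delivery_date - 7 * gestation_weeks` days, to 12 months after
#' delivery, implemented as `delivery_date + 365` days. Both endpoints are
#' inclusive: a cancer dated on the delivery day or on the 365th day after it
#' is pregnancy-associated.
#'
#' @param maternities data.frame with columns `woman_id`, `maternity_id`,
#'   `delivery_date` (`Date` or ISO-8601 string), `gestation_weeks`
#'   (completed weeks, 20-44; births under 20 weeks are not in scope of the
#'   birth data).
#' @return data.frame with columns `maternity_id`, `woman_id`,
#'   `delivery_date`, `gestation_weeks`, `start_date`, `end_date`.
#' @examples
#' m <- data.frame(woman_id = "w1", maternity_id = "m1",
#'                 delivery_date = "2004-06-30", gestation_weeks = 40)
#' make_window(m)
#' @export
make_window <- function(maternities) {
  stopifnot_cols(maternities,
                 c("woman_id", "maternity_id", "delivery_date", "gestation_weeks"),
                 "maternity data")
  dd <- if (inherits(maternities$delivery_date, "Date")) maternities$delivery_date
        else parse_iso_date(maternities$delivery_date, "delivery_date")
  gw <- as.integer(maternities$gestation_weeks)
  bad <- which(is.na(gw) | gw < 20L | gw > 44L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "gestation_weeks outside [20, 44] for maternity %s (row %d): %s",
      as.character(maternities$maternity_id[bad[1L]]), bad[1L],
      as.character(maternities$gestation_weeks[bad[1L]])), call. = FALSE)
  }
  data.frame(
    maternity_id = maternities$maternity_id,
    woman_id = maternities$woman_id,
    delivery_date = dd,
    gestation_weeks = gw,
    start_date = dd - 7L * gw,
    end_date = dd + 365L,
    stringsAsFactors = FALSE
  )
}

#' Attribute dated events to maternities
#'
#' Finds, for each event, the exposure window of the same woman containing
#' the event date. When consecutive windows of one woman overlap (a new
#' pregnancy within 12 months of a delivery) and an event falls in both, the
#' maternity with the earliest delivery date wins under `rule = "earliest"`;
#' `rule = "all"` returns every containing maternity.
#'
#' @param woman_id,event_date vectors of equal length identifying the events.
#' @param windows window table from [make_window()].
#' @param rule `"earliest"` (default) or `"all"`.
#' @return for `"earliest"`, a character vector of `maternity_id` (NA when no
#'   window contains the event), aligned with the input events; for `"all"`,
#'   a data.frame of `(event, maternity_id)` pairs where `event` indexes the
#'   input.
#' @export
attribute_event <- function(woman_id, event_date, windows,
                            rule = c("earliest", "all")) {
  rule <- match.arg(rule)
  stopifnot(length(woman_id) == length(event_date))
  if (length(woman_id) == 0L) {
    return(if (rule == "earliest") character(0)
           else data.frame(event = integer(0), maternity_id = character(0)))
  }
  ev <- data.frame(.ev = seq_along(woman_id),
                   woman_id = as.character(woman_id),
                   date = as.Date(event_date), stringsAsFactors = FALSE)
  w <- windows[, c("maternity_id", "woman_id", "delivery_date",
                   "start_date", "end_date")]
  w$woman_id <- as.character(w$woman_id)
  mm <- merge(ev, w, by = "woman_id")
  mm <- mm[mm$date >= mm$start_date & mm$date <= mm$end_date, , drop = FALSE]
  if (rule == "all") {
    mm <- mm[order(mm$.ev, mm$delivery_date, mm$maternity_id), , drop = FALSE]
    return(data.frame(event = mm$.ev,
                      maternity_id = as.character(mm$maternity_id),
                      stringsAsFactors = FALSE))
  }
  mm <- mm[order(mm$.ev, mm$delivery_date, mm$maternity_id), , drop = FALSE]
  first <- mm[!duplicated(mm$.ev), , drop = FALSE]
  out <- rep(NA_character_, length(woman_id))
  out[first$.ev] <- as.character(first$maternity_id)
  out
}
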