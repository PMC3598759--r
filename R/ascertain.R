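# Construction of the three comparable case sets. The unit of comparison is
# the (maternity, clinical group) pair for registry and hospital-index cases;
# "all cancer hospitalisations" counts qualifying records.

#' Registry gold-standard cases
#'
#' Attributes incident registry cancers to maternities. A registry record
#' contributes a case when (i) its diagnosis date falls in a maternity
#' exposure window of the same woman and (ii) it is incident rather than
#' prevalent, i.e. its earliest notification of that group equals the
#' diagnosis date (lookback semantics). Duplicate notifications of one group
#' within one maternity collapse to the earliest diagnosis; distinct groups
#' within one maternity yield distinct cases (multiple primary cancers in a
#' pregnancy are kept).
#'
#' @param registry registry data.frame (see [read_registry()]).
#' @param windows window table from [make_window()].
#' @param rule attribution rule passed to [attribute_event()].
#' @return data.frame of cases: `maternity_id`, `group`, `source`
#'   (`"registry"`), `event_date`, `source_record_id`, `woman_id`.
#' @export
registry_cases <- function(registry, windows, rule = "earliest") {
  reg <- registry[registry$first_notification_date == registry$diagnosis_date, ,
                  drop = FALSE]
  mat <- attribute_event(reg$woman_id, reg$diagnosis_date, windows, rule = rule)
  keep <- !is.na(mat)
  cases <- data.frame(
    maternity_id = mat[keep],
    group = reg$group[keep],
    source = "registry",
    event_date = as.Date(reg$diagnosis_date[keep]),
    source_record_id = as.character(reg$registry_id[keep]),
    woman_id = as.character(reg$woman_id[keep]),
    stringsAsFactors = FALSE
  )
  dedupe_earliest(cases)
}

#' Hospital "all cancer hospitalisations" cases
#'
#' Every hospital record whose admission date attributes to an exposure
#' window and whose diagnosis fields contain at least one incident-candidate
#' cancer code yields one case; the record, not the woman, is the unit.
#' The record's group is that of the first-listed eligible code
#' ([record_group()]).
#'
#' @param hospital hospital data.frame (see [read_hospital()]).
#' @param windows window table from [make_window()].
#' @param map a `code_map`.
#' @param rule attribution rule.
#' @return data.frame of cases with `source = "hospital_all"`, one row per
#'   qualifying record.
#' @export
hospital_all_cases <- function(hospital, windows, map = default_code_map(),
                               rule = "earliest") {
  dcols <- grep("^diag[0-9]+$", names(hospital), value = TRUE)
  dcols <- dcols[order(as.integer(sub("^diag", "", dcols)))]
  if (nrow(hospital) == 0L) {
    return(empty_cases("hospital_all"))
  }
  grp <- record_group_matrix(as.matrix(hospital[, dcols, drop = FALSE]), map)
  keep1 <- !is.na(grp)
  h <- hospital[keep1, , drop = FALSE]
  mat <- attribute_event(h$woman_id, h$admission_date, windows, rule = rule)
  keep2 <- !is.na(mat)
  data.frame(
    maternity_id = mat[keep2],
    group = grp[keep1][keep2],
    source = "hospital_all",
    event_date = as.Date(h$admission_date[keep2]),
    source_record_id = as.character(h$record_id[keep2]),
    woman_id = as.character(h$woman_id[keep2]),
    stringsAsFactors = FALSE
  )
}

#' Hospital "index cancer hospitalisation" cases
#'
#' Reduces the all-hospitalisations list to one case per (maternity, group):
#' the record with the earliest admission date, ties broken by smallest
#' record id. This replicates ascertainment when individuals are
#' identifiable and the first cancer admission is taken as the incident
#' event.
#'
#' @inheritParams hospital_all_cases
#' @return data.frame of cases with `source = "hospital_index"`, unique on
#'   (`maternity_id`, `group`).
#' @export
hospital_index_cases <- function(hospital, windows, map = default_code_map(),
                                 rule = "earliest") {
  all_cases <- hospital_all_cases(hospital, windows, map, rule)
  idx <- dedupe_earliest(all_cases)
  idx$source <- rep("hospital_index", nrow(idx))
  idx
}

# Keep, per (maternity_id, group), the earliest event_date; ties broken by
# smallest source_record_id (numeric when possible, else lexicographic).
dedupe_earliest <- function(cases) {
  if (nrow(cases) == 0L) return(cases)
  rid <- suppressWarnings(as.numeric(cases$source_record_id))
  ord <- if (anyNA(rid)) {
    order(cases$maternity_id, cases$group, cases$event_date,
          cases$source_record_id)
  } else {
    order(cases$maternity_id, cases$group, cases$event_date, rid)
  }
  cases <- cases[ord, , drop = FALSE]
  key <- paste(cases$maternity_id, cases$group, sep = "\r")
  out <- cases[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_cases <- function(source) {
  data.frame(maternity_id = character(0), group = character(0),
             source = character(0), event_date = as.Date(character(0)),
             source_record_id = character(0), woman_id = character(0),
             stringsAsFactors = FALSE)
}
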