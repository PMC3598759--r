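# Brute-force oracles written directly from the definitions, kept
# deliberately independent of the package internals (scalar loops, explicit
# set algebra). Used for randomized equivalence testing on small cohorts.

# Scalar code classification by explicit range checks.
oracle_classify <- function(code) {
  up <- toupper(gsub("[. ]", "", trimws(code)))
  if (!grepl("^[A-Z][0-9][0-9]", up)) stop("malformed")
  if (substr(up, 1, 1) != "C") return("out_of_scope")
  n <- as.integer(substr(up, 2, 3))
  if (n >= 77 && n <= 79) return("secondary")
  if (n == 44) return("out_of_scope")
  if (n <= 14 || (n >= 30 && n <= 32)) return("head_neck")
  if ((n >= 15 && n <= 17) || (n >= 22 && n <= 29)) return("upper_gi")
  if (n >= 18 && n <= 21) return("colorectal")
  if (n >= 33 && n <= 39) return("respiratory")
  if ((n >= 40 && n <= 42) || (n >= 45 && n <= 49)) return("bone_connective")
  if (n == 43) return("melanoma")
  if (n == 50) return("breast")
  if (n >= 51 && n <= 59) return("gynaecological")
  if (n >= 60 && n <= 68) return("urogenital")
  if (n >= 69 && n <= 72) return("neurological")
  if (n >= 73 && n <= 75) return("thyroid_endocrine")
  if (n == 76 || n == 80) return("ill_defined_unknown")
  "lymphohaematopoeitic"
}

# Loop-based window attribution (earliest delivery among containing windows).
oracle_attribute <- function(woman_id, event_date, windows) {
  best <- NA_character_
  best_del <- as.Date(NA)
  for (i in seq_len(nrow(windows))) {
    if (windows$woman_id[i] == woman_id &&
        event_date >= windows$start_date[i] &&
        event_date <= windows$end_date[i]) {
      if (is.na(best) || windows$delivery_date[i] < best_del ||
          (windows$delivery_date[i] == best_del &&
           windows$maternity_id[i] < best)) {
        best <- windows$maternity_id[i]
        best_del <- windows$delivery_date[i]
      }
    }
  }
  best
}

# Case sets built record by record from the definitions.
oracle_registry_cases <- function(registry, windows) {
  out <- list()
  for (i in seq_len(nrow(registry))) {
    if (registry$first_notification_date[i] != registry$diagnosis_date[i]) next
    m <- oracle_attribute(registry$woman_id[i], registry$diagnosis_date[i],
                          windows)
    if (is.na(m)) next
    key <- paste(m, registry$group[i])
    if (is.null(out[[key]]) || registry$diagnosis_date[i] < out[[key]]$date) {
      out[[key]] <- list(maternity = m, group = registry$group[i],
                         date = registry$diagnosis_date[i])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(maternity_id = character(0), group = character(0)))
  }
  data.frame(maternity_id = vapply(out, `[[`, "", "maternity"),
             group = vapply(out, `[[`, "", "group"),
             row.names = NULL, stringsAsFactors = FALSE)
}

oracle_hospital_all <- function(hospital, windows) {
  dcols <- grep("^diag", names(hospital), value = TRUE)
  rows <- list()
  for (i in seq_len(nrow(hospital))) {
    grp <- NA_character_
    for (cc in dcols) {
      code <- hospital[[cc]][i]
      if (is.na(code) || !nzchar(trimws(code))) next
      cl <- oracle_classify(code)
      if (!cl %in% c("secondary", "out_of_scope")) { grp <- cl; break }
    }
    if (is.na(grp)) next
    m <- oracle_attribute(hospital$woman_id[i], hospital$admission_date[i],
                          windows)
    if (is.na(m)) next
    rows[[length(rows) + 1L]] <-
      data.frame(maternity_id = m, group = grp,
                 admission_date = hospital$admission_date[i],
                 record_id = as.numeric(hospital$record_id[i]),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(maternity_id = character(0), group = character(0),
                      admission_date = as.Date(character(0)),
                      record_id = numeric(0)))
  }
  do.call(rbind, rows)
}

oracle_hospital_index <- function(hospital, windows) {
  all_c <- oracle_hospital_all(hospital, windows)
  keep <- list()
  for (i in seq_len(nrow(all_c))) {
    key <- paste(all_c$maternity_id[i], all_c$group[i])
    cur <- keep[[key]]
    if (is.null(cur) ||
        all_c$admission_date[i] < cur$admission_date ||
        (all_c$admission_date[i] == cur$admission_date &&
         all_c$record_id[i] < cur$record_id)) {
      keep[[key]] <- all_c[i, ]
    }
  }
  if (length(keep) == 0L) return(all_c)
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

oracle_cross_classify <- function(index, registry, n_mat, group) {
  ik <- paste(index$maternity_id, index$group)[index$group == group]
  rk <- paste(registry$maternity_id, registry$group)[registry$group == group]
  tp <- sum(ik %in% rk)
  c(tp = tp, fp = length(ik) - tp, fn = length(rk) - tp,
    tn = n_mat - tp - (length(ik) - tp) - (length(rk) - tp))
}

# Small random linked cohort (independent of simulate_cohort): random
# windows, admissions with a mixed code pool, registry rows that are
# sometimes prevalent (earlier first notification).
random_small_cohort <- function(n_women = 30) {
  n_mat_per <- sample(1:2, n_women, replace = TRUE)
  woman <- rep(sprintf("w%02d", seq_len(n_women)), n_mat_per)
  n <- length(woman)
  delivery <- as.Date("2003-01-01") + sample(0:1800, n, replace = TRUE)
  maternities <- data.frame(
    woman_id = woman, maternity_id = sprintf("m%03d", seq_len(n)),
    delivery_date = delivery,
    gestation_weeks = sample(20:44, n, replace = TRUE),
    stringsAsFactors = FALSE)
  pool <- c("C43.1", "C50.9", "C18.0", "C81.2", "C71.9", "C78.0", "D05.1",
            "O80", "Z37.0", "C16.1", "C64.9", "C34.1")
  nh <- 3L * n
  hospital <- data.frame(
    woman_id = sample(c(woman, "stranger"), nh, replace = TRUE),
    record_id = sample(1000:9999, nh),
    admission_date = as.Date("2002-06-01") + sample(0:2500, nh, replace = TRUE),
    diag1 = sample(pool, nh, replace = TRUE),
    diag2 = sample(c(pool, ""), nh, replace = TRUE),
    stringsAsFactors = FALSE)
  nr <- n
  diag <- as.Date("2002-06-01") + sample(0:2500, nr, replace = TRUE)
  prevalent <- runif(nr) < 0.25
  registry <- data.frame(
    woman_id = sample(c(woman, "stranger"), nr, replace = TRUE),
    registry_id = sprintf("R%03d", seq_len(nr)),
    diagnosis_date = diag,
    group = sample(clinical_groups(), nr, replace = TRUE),
    first_notification_date = diag - ifelse(prevalent,
                                            sample(200:3000, nr, TRUE), 0L),
    stringsAsFactors = FALSE)
  list(maternities = maternities, hospital = hospital, registry = registry)
}
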