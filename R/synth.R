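# Seeded synthetic linked-cohort generator. Emulates the statistical
# structure of three linked collections (maternity, hospital, registry):
# per-group registry incidence, per-group hospital capture, admission
# multiplicity, admission-before-registration timing offsets, and the three
# false-positive mechanisms (prevalent cancers, miscoded type, uncorroborated
# noise), plus optional linkage-error noise. A truth ledger records every
# planted event and the expected cross-classification absent linkage noise.

#' Generator configuration
#'
#' Returns the default configuration of the synthetic cohort generator, with
#' any field overridable via `...`. Defaults encode the reference cohort's
#' statistical structure ([nsw_reference_counts()]): per-group registry
#' incidence on the 679,736-maternity scale, per-group hospital capture
#' probabilities (the reference sensitivities tp/(tp+fn)), mean extra
#' admissions per captured cancer (the all/index ratio minus one),
#' the 66/28/5/1 percent timing mixture over admission-before-registration
#' month bins, false-positive planting rates (86 prevalent, 22 miscoded and
#' 58 unexplained per 679,736 maternities), and probabilistic-linkage error
#' rates of 3/1,000 false and 5/1,000 missed links.
#'
#' @param ... named overrides of any default field.
#' @return an object of class `pac_config` (a named list).
#' @examples
#' cfg <- pac_config(fp_noise_rate = 0, linkage_missed_rate = 0)
#' @export
pac_config <- function(...) {
  ref <- nsw_reference_counts()
  n_ref <- as.numeric(attr(ref, "n_maternities"))
  groups <- clinical_groups()
  named <- function(x) stats::setNames(as.numeric(x), groups)

  gest_p <- c(rep(0.0004, 8),                       # 20-27 weeks
              rep(0.0015, 4),                       # 28-31
              0.004, 0.005, 0.008, 0.012, 0.020,    # 32-36
              0.045, 0.13, 0.24, 0.30, 0.16,        # 37-41
              0.05, 0.01, 0.002)                    # 42-44
  # prevalent FPs: lymphohaematopoeitic 38, breast 14, melanoma 13,
  # thyroid 10 of 86; remainder uniform over the other nine groups
  prev <- named(c(13, 14, 10, 11 / 9, 38, rep(11 / 9, 8)))
  # miscode sources: colorectal 7, gynaecological 4, melanoma 3 of 22;
  # remainder uniform over the other ten groups
  misc <- named(rep(8 / 10, 13))
  misc["melanoma"] <- 3; misc["colorectal"] <- 7; misc["gynaecological"] <- 4

  cfg <- list(
    study_start = as.Date("2001-01-01"),
    study_end = as.Date("2008-12-31"),
    maternities_per_woman = c(`1` = 0.62, `2` = 0.32, `3` = 0.055, `4` = 0.005),
    interpregnancy_gap_days = c(400L, 1100L),
    gestation_weeks = stats::setNames(gest_p / sum(gest_p), 20:44),
    group_incidence = named(1e5 * ref$registry_n / n_ref),
    capture_prob = named(ref$tp / (ref$tp + ref$fn)),
    extra_admissions_mean = named(ref$hospital_all_n / ref$hospital_index_n - 1),
    timing_mixture = c(same_month = 0.66, prior_1_2 = 0.28,
                       prior_3_5 = 0.05, prior_6_plus = 0.01),
    fp_prevalent_rate = 86 / n_ref,
    fp_miscode_rate = 22 / n_ref,
    fp_noise_rate = 58 / n_ref,
    prevalent_group_probs = prev / sum(prev),
    miscode_source_probs = misc / sum(misc),
    miscode_confusion = list(colorectal = c(upper_gi = 1),
                             gynaecological = c(upper_gi = 1),
                             melanoma = c(breast = 0.5, bone_connective = 0.5)),
    noise_group_probs = named(ref$fp / sum(ref$fp)),
    linkage_missed_rate = 5 / 1000,
    linkage_false_rate = 3 / 1000,
    background_admissions = TRUE,
    lookback_start = as.Date("1994-01-01")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "pac_config"))
}

validate_config <- function(cfg) {
  probs <- c(cfg$capture_prob, cfg$fp_prevalent_rate, cfg$fp_miscode_rate,
             cfg$fp_noise_rate, cfg$linkage_missed_rate, cfg$linkage_false_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$group_incidence < 0) || any(cfg$extra_admissions_mean < 0)) {
    stop("rates and admission means must be non-negative", call. = FALSE)
  }
  for (f in c("maternities_per_woman", "gestation_weeks", "timing_mixture",
              "prevalent_group_probs", "miscode_source_probs",
              "noise_group_probs")) {
    s <- sum(cfg[[f]])
    if (s <= 0) stop(f, " must have positive mass", call. = FALSE)
    cfg[[f]] <- cfg[[f]] / s
  }
  if (cfg$study_end <= cfg$study_start) {
    stop("study_end must be after study_start", call. = FALSE)
  }
  cfg
}

#' @export
print.pac_config <- function(x, ...) {
  cat("Synthetic linked-cohort generator configuration\n")
  cat(sprintf("  study period %s .. %s; lookback from %s\n",
              x$study_start, x$study_end, x$lookback_start))
  cat(sprintf("  overall registry incidence %.1f/100,000 maternities over 13 groups\n",
              sum(x$group_incidence)))
  cat(sprintf("  capture probabilities %.2f-%.2f; FP rates (prevalent/miscode/noise) %.2g/%.2g/%.2g\n",
              min(x$capture_prob), max(x$capture_prob),
              x$fp_prevalent_rate, x$fp_miscode_rate, x$fp_noise_rate))
  cat(sprintf("  timing mixture: %s\n",
              paste(sprintf("%s %.0f%%", names(x$timing_mixture),
                            100 * x$timing_mixture), collapse = ", ")))
  cat(sprintf("  linkage error: %.3g missed, %.3g false per record\n",
              x$linkage_missed_rate, x$linkage_false_rate))
  invisible(x)
}

#' Read / write a generator configuration
#'
#' YAML serialization of [pac_config()] objects; the packaged default is at
#' `system.file("extdata", "generator_defaults.yaml", package = "pacvalid")`.
#' Fields absent from the file keep their defaults.
#'
#' @param path file path.
#' @return `read_generator_config()` returns a `pac_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("study_start", "study_end", "lookback_start")) {
    if (!is.null(y[[f]])) y[[f]] <- as.Date(y[[f]])
  }
  for (f in c("maternities_per_woman", "gestation_weeks", "group_incidence",
              "capture_prob", "extra_admissions_mean", "timing_mixture",
              "prevalent_group_probs", "miscode_source_probs",
              "noise_group_probs")) {
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  }
  if (!is.null(y$miscode_confusion)) {
    y$miscode_confusion <- lapply(y$miscode_confusion, unlist)
  }
  do.call(pac_config, y)
}

#' @rdname read_generator_config
#' @param config a `pac_config`.
#' @export
write_generator_config <- function(config, path) {
  y <- unclass(config)
  for (f in c("study_start", "study_end", "lookback_start")) {
    y[[f]] <- format(y[[f]])
  }
  for (f in names(y)) {
    if (is.numeric(y[[f]]) && !is.null(names(y[[f]]))) y[[f]] <- as.list(y[[f]])
  }
  y$miscode_confusion <- lapply(y$miscode_confusion, as.list)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

# Representative ICD-10-AM code stems per clinical group (dot-suffix
# subdivisions are drawn at random).
group_code_stems <- list(
  melanoma = "C43", breast = "C50", thyroid_endocrine = c("C73", "C75"),
  gynaecological = c("C53", "C56"), lymphohaematopoeitic = c("C81", "C91", "C83"),
  colorectal = c("C18", "C20"), neurological = c("C71", "C70"),
  bone_connective = c("C41", "C49"), head_neck = c("C11", "C32"),
  upper_gi = c("C16", "C25"), respiratory = "C34",
  ill_defined_unknown = "C80", urogenital = c("C64", "C67")
)

sample_group_code <- function(groups) {
  stems <- vapply(groups, function(g) {
    s <- group_code_stems[[g]]
    s[sample.int(length(s), 1L)]
  }, character(1))
  paste0(stems, ".", sample(0:8, length(groups), replace = TRUE))
}

sample_cat <- function(n, probs) {
  if (n == 0L) return(character(0))
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

runif_date <- function(a, b) {
  span <- as.integer(as.Date(b) - as.Date(a)) + 1L
  as.Date(a) + floor(stats::runif(length(span)) * pmax(span, 1L))
}

# Admission date a whole-month offset before a registry date: same calendar
# month (day <= registry day) for offset 0, otherwise a uniform day in the
# month `m` calendar months earlier; clamped to the window start.
offset_admission <- function(registry_date, months_before, window_start) {
  lt <- as.POSIXlt(registry_date)
  tmi <- month_index(registry_date) - months_before
  oy <- tmi %/% 12L
  om <- tmi %% 12L
  ndays <- days_in_month(oy, om)
  maxday <- ifelse(months_before == 0L, lt$mday, ndays)
  day <- 1L + floor(stats::runif(length(registry_date)) * maxday)
  adm <- as.Date(sprintf("%04d-%02d-%02d", oy, om + 1L, day))
  clamped <- adm < window_start
  adm[clamped] <- window_start[clamped]
  list(date = adm, clamped = clamped)
}

#' Generate a synthetic linked cohort
#'
#' Draws women, maternities and delivery dates over the study period, plants
#' incident registry cancers per (maternity, group) at the configured
#' incidence, captures each in hospital data with the configured probability
#' (index admission preceding the registry date by a month offset from the
#' timing mixture, plus extra same-group admissions), plants the three
#' false-positive mechanisms (prevalent cancers with pre-window registry
#' history, miscoded cancer types, uncorroborated noise admissions) and,
#' optionally, linkage errors. Every maternity also receives a non-cancer
#' delivery admission when `background_admissions` is on.
#'
#' With the same seed and configuration the output is identical draw for
#' draw (and byte for byte once written with the `write_*` functions).
#'
#' @param n_women number of women to simulate.
#' @param config a [pac_config()].
#' @param seed integer seed; when non-NULL the global RNG state is saved and
#'   restored.
#' @return list with data.frames `maternities`, `hospital`, `registry`, the
#'   `ledger` (see [truth_summary()]), and the `config` used.
#' @export
simulate_cohort <- function(n_women = 2000L, config = pac_config(),
                            seed = NULL) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  cfg <- validate_config(config)
  groups <- clinical_groups()

  ## --- maternities -------------------------------------------------------
  k <- as.integer(sample_cat(n_women, cfg$maternities_per_woman))
  woman <- rep(sprintf("W%06d", seq_len(n_women)), k)
  idx_in_woman <- sequence(k)
  n0 <- length(woman)
  first <- rep(runif_date(rep(cfg$study_start, n_women), rep(cfg$study_end, n_women)),
               k)
  gap <- ifelse(idx_in_woman == 1L, 0,
                cfg$interpregnancy_gap_days[1L] +
                  floor(stats::runif(n0) *
                          (diff(cfg$interpregnancy_gap_days) + 1L)))
  cumgap <- stats::ave(gap, woman, FUN = cumsum)
  delivery <- first + cumgap
  keep <- delivery <= cfg$study_end
  maternities <- data.frame(
    woman_id = woman[keep],
    maternity_id = sprintf("M%07d", seq_len(sum(keep))),
    delivery_date = delivery[keep],
    gestation_weeks = as.integer(sample_cat(sum(keep), cfg$gestation_weeks)),
    stringsAsFactors = FALSE
  )
  windows <- make_window(maternities)
  n_mat <- nrow(windows)

  ## --- incident registry cancers per (maternity, group) ------------------
  plant <- list()
  for (g in groups) {
    p <- cfg$group_incidence[[g]] / 1e5
    sel <- which(stats::runif(n_mat) < p)
    if (length(sel) > 0L) {
      plant[[g]] <- data.frame(row = sel, group = g, mechanism = "incident",
                               stringsAsFactors = FALSE)
    }
  }
  ## miscoded cancers: a true incident cancer whose admission carries a
  ## different group's code
  sel <- which(stats::runif(n_mat) < cfg$fp_miscode_rate)
  if (length(sel) > 0L) {
    plant$miscode <- data.frame(row = sel,
                                group = sample_cat(length(sel),
                                                   cfg$miscode_source_probs),
                                mechanism = "miscode_true",
                                stringsAsFactors = FALSE)
  }
  true_cancers <- if (length(plant) > 0L) do.call(rbind, plant)
                  else data.frame(row = integer(0), group = character(0),
                                  mechanism = character(0))
  rownames(true_cancers) <- NULL
  ntc <- nrow(true_cancers)
  ws <- windows$start_date[true_cancers$row]
  we <- windows$end_date[true_cancers$row]
  diag_date <- ws + floor(stats::runif(ntc) * (as.integer(we - ws) + 1L))
  true_cancers$diagnosis_date <- diag_date
  true_cancers$maternity_id <- windows$maternity_id[true_cancers$row]
  true_cancers$woman_id <- windows$woman_id[true_cancers$row]

  ## --- hospital capture with timing offsets ------------------------------
  is_incident <- true_cancers$mechanism == "incident"
  captured <- rep(FALSE, ntc)
  captured[is_incident] <- stats::runif(sum(is_incident)) <
    cfg$capture_prob[true_cancers$group[is_incident]]
  captured[!is_incident] <- TRUE  # miscode mechanism presupposes an admission

  adm <- list()
  cap <- which(captured)
  if (length(cap) > 0L) {
    bin <- sample_cat(length(cap), cfg$timing_mixture)
    months <- integer(length(cap))
    months[bin == "prior_1_2"] <- sample(1:2, sum(bin == "prior_1_2"), TRUE)
    months[bin == "prior_3_5"] <- sample(3:5, sum(bin == "prior_3_5"), TRUE)
    months[bin == "prior_6_plus"] <- sample(6:9, sum(bin == "prior_6_plus"), TRUE)
    off <- offset_admission(true_cancers$diagnosis_date[cap], months,
                            windows$start_date[true_cancers$row[cap]])
    coded_group <- true_cancers$group[cap]
    mis <- true_cancers$mechanism[cap] == "miscode_true"
    if (any(mis)) {
      coded_group[mis] <- vapply(coded_group[mis], function(g) {
        conf <- cfg$miscode_confusion[[g]]
        if (is.null(conf)) sample(setdiff(groups, g), 1L)
        else sample_cat(1L, conf)
      }, character(1))
    }
    realized <- month_diff(true_cancers$diagnosis_date[cap], off$date)
    adm$index <- data.frame(
      row = true_cancers$row[cap], group = coded_group,
      mechanism = ifelse(mis, "miscode_fp", "index"),
      admission_date = off$date, clamped = off$clamped,
      realized_months = realized, cancer = cap,
      stringsAsFactors = FALSE
    )
    ## extra admissions for captured (correctly coded) cancers, never earlier
    ## than the index admission so the index stays the incident event
    ok <- which(!mis)
    nex <- stats::rpois(length(ok),
                        cfg$extra_admissions_mean[coded_group[ok]])
    if (sum(nex) > 0L) {
      rep_i <- rep(ok, nex)
      lo <- off$date[rep_i]
      hi <- windows$end_date[true_cancers$row[cap][rep_i]]
      edate <- lo + floor(stats::runif(length(rep_i)) *
                            (as.integer(hi - lo) + 1L))
      adm$extra <- data.frame(
        row = true_cancers$row[cap][rep_i], group = coded_group[rep_i],
        mechanism = "extra", admission_date = edate, clamped = FALSE,
        realized_months = NA_integer_, cancer = cap[rep_i],
        stringsAsFactors = FALSE
      )
    }
  }

  ## --- prevalent-cancer false positives -----------------------------------
  sel <- which(stats::runif(n_mat) < cfg$fp_prevalent_rate)
  prevalent_hist <- NULL
  if (length(sel) > 0L) {
    g <- sample_cat(length(sel), cfg$prevalent_group_probs)
    ## notify strictly before the woman's earliest window so the historic
    ## record can never be incident-in-window for any of her maternities
    wmin <- tapply(as.integer(windows$start_date), windows$woman_id, min)
    hi <- as.Date(as.integer(wmin[windows$woman_id[sel]]),
                  origin = "1970-01-01") - 30L
    lo <- pmax(as.integer(cfg$lookback_start), as.integer(hi) - 15L * 365L)
    notif <- as.Date(lo + floor(stats::runif(length(sel)) *
                                  (as.integer(hi) - lo + 1L)),
                     origin = "1970-01-01")
    prevalent_hist <- data.frame(
      row = sel, group = g, mechanism = "prevalent_history",
      diagnosis_date = notif, maternity_id = windows$maternity_id[sel],
      woman_id = windows$woman_id[sel], stringsAsFactors = FALSE
    )
    adate <- windows$start_date[sel] +
      floor(stats::runif(length(sel)) *
              (as.integer(windows$end_date[sel] - windows$start_date[sel]) + 1L))
    adm$prevalent <- data.frame(
      row = sel, group = g, mechanism = "prevalent_fp",
      admission_date = adate, clamped = FALSE,
      realized_months = NA_integer_, cancer = NA_integer_,
      stringsAsFactors = FALSE
    )
  }

  ## --- noise false positives ----------------------------------------------
  sel <- which(stats::runif(n_mat) < cfg$fp_noise_rate)
  if (length(sel) > 0L) {
    adate <- windows$start_date[sel] +
      floor(stats::runif(length(sel)) *
              (as.integer(windows$end_date[sel] - windows$start_date[sel]) + 1L))
    adm$noise <- data.frame(
      row = sel, group = sample_cat(length(sel), cfg$noise_group_probs),
      mechanism = "noise_fp", admission_date = adate, clamped = FALSE,
      realized_months = NA_integer_, cancer = NA_integer_,
      stringsAsFactors = FALSE
    )
  }

  admissions <- if (length(adm) > 0L) do.call(rbind, adm)
                else data.frame(row = integer(0), group = character(0),
                                mechanism = character(0),
                                admission_date = as.Date(character(0)),
                                clamped = logical(0),
                                realized_months = integer(0),
                                cancer = integer(0))
  rownames(admissions) <- NULL
  admissions$maternity_id <- windows$maternity_id[admissions$row]
  admissions$woman_id <- windows$woman_id[admissions$row]

  ## --- hospital table ------------------------------------------------------
  nadm <- nrow(admissions)
  code <- sample_group_code(admissions$group)
  secondary_field <- stats::runif(nadm) < 0.3  # cancer code not in field 1
  hosp_cancer <- data.frame(
    woman_id = admissions$woman_id,
    admission_date = admissions$admission_date,
    diag1 = ifelse(secondary_field, "O26.8", code),
    diag2 = ifelse(secondary_field, code, "Z51.1"),
    stringsAsFactors = FALSE
  )
  hospital <- hosp_cancer
  if (isTRUE(cfg$background_admissions)) {
    bg <- data.frame(
      woman_id = maternities$woman_id,
      admission_date = maternities$delivery_date,
      diag1 = "O80", diag2 = "Z37.0",
      stringsAsFactors = FALSE
    )
    hospital <- rbind(hosp_cancer, bg)
  }
  ord <- order(hospital$admission_date, hospital$woman_id)
  hospital <- hospital[ord, , drop = FALSE]
  hospital$record_id <- seq_len(nrow(hospital))
  hospital <- hospital[, c("woman_id", "record_id", "admission_date",
                           "diag1", "diag2")]
  rownames(hospital) <- NULL
  admissions$record_id <- hospital$record_id[
    match(seq_len(nadm), ord)]

  ## --- registry table ------------------------------------------------------
  reg_parts <- list(
    data.frame(woman_id = true_cancers$woman_id,
               diagnosis_date = true_cancers$diagnosis_date,
               group = true_cancers$group,
               first_notification_date = true_cancers$diagnosis_date,
               mechanism = true_cancers$mechanism,
               maternity_id = true_cancers$maternity_id,
               stringsAsFactors = FALSE)
  )
  if (!is.null(prevalent_hist)) {
    reg_parts$prev <- data.frame(
      woman_id = prevalent_hist$woman_id,
      diagnosis_date = prevalent_hist$diagnosis_date,
      group = prevalent_hist$group,
      first_notification_date = prevalent_hist$diagnosis_date,
      mechanism = "prevalent_history",
      maternity_id = prevalent_hist$maternity_id,
      stringsAsFactors = FALSE
    )
  }
  registry_full <- do.call(rbind, reg_parts)
  rownames(registry_full) <- NULL
  ord <- order(registry_full$diagnosis_date, registry_full$woman_id)
  registry_full <- registry_full[ord, , drop = FALSE]
  registry_full$registry_id <- sprintf("R%06d", seq_len(nrow(registry_full)))

  ## --- linkage noise -------------------------------------------------------
  linked_woman <- registry_full$woman_id
  if (cfg$linkage_missed_rate > 0 && nrow(registry_full) > 0L) {
    wm <- unique(registry_full$woman_id)
    missed <- wm[stats::runif(length(wm)) < cfg$linkage_missed_rate]
    hit <- linked_woman %in% missed
    linked_woman[hit] <- paste0("X", linked_woman[hit])
  }
  if (cfg$linkage_false_rate > 0 && nrow(registry_full) > 0L) {
    fl <- which(stats::runif(nrow(registry_full)) < cfg$linkage_false_rate)
    if (length(fl) > 0L) {
      linked_woman[fl] <- maternities$woman_id[
        1L + floor(stats::runif(length(fl)) * nrow(maternities))]
    }
  }
  registry <- data.frame(
    woman_id = linked_woman,
    registry_id = registry_full$registry_id,
    diagnosis_date = registry_full$diagnosis_date,
    group = registry_full$group,
    first_notification_date = registry_full$first_notification_date,
    stringsAsFactors = FALSE
  )

  ## --- truth ledger --------------------------------------------------------
  ledger <- build_ledger(registry_full, admissions, windows, captured,
                         true_cancers)
  ledger$config <- cfg
  ledger$seed <- seed

  list(maternities = maternities, hospital = hospital, registry = registry,
       ledger = ledger, config = cfg)
}

# Expected cross-classification absent linkage noise, from the planted
# events: registry and hospital (maternity, group) sets are formed with the
# same attribution rule the analysis uses, then intersected.
build_ledger <- function(registry_full, admissions, windows, captured,
                         true_cancers) {
  groups <- clinical_groups()
  inc <- registry_full[registry_full$mechanism != "prevalent_history", ,
                       drop = FALSE]
  reg_attr <- attribute_event(inc$woman_id, inc$diagnosis_date, windows)
  rkey <- unique(paste(reg_attr, inc$group, sep = "\r")[!is.na(reg_attr)])
  adm_attr <- attribute_event(admissions$woman_id, admissions$admission_date,
                              windows)
  ikey <- unique(paste(adm_attr, admissions$group, sep = "\r")[!is.na(adm_attr)])
  split_grp <- function(keys) sub("^.*\r", "", keys)
  expected <- data.frame(group = groups, tp = 0L, fp = 0L, fn = 0L,
                         stringsAsFactors = FALSE)
  tpg <- split_grp(intersect(ikey, rkey))
  fpg <- split_grp(setdiff(ikey, rkey))
  fng <- split_grp(setdiff(rkey, ikey))
  for (i in seq_along(groups)) {
    g <- groups[i]
    expected[i, c("tp", "fp", "fn")] <-
      c(sum(tpg == g), sum(fpg == g), sum(fng == g))
  }
  timing_tally <- stats::setNames(integer(4),
                                  c("same_month", "prior_1_2", "prior_3_5",
                                    "prior_6_plus"))
  mi <- admissions$realized_months[admissions$mechanism == "index"]
  if (length(mi) > 0L) {
    timing_tally["same_month"] <- sum(mi == 0L)
    timing_tally["prior_1_2"] <- sum(mi >= 1L & mi <= 2L)
    timing_tally["prior_3_5"] <- sum(mi >= 3L & mi <= 5L)
    timing_tally["prior_6_plus"] <- sum(mi >= 6L)
  }
  list(
    registry_events = registry_full,
    admission_events = admissions,
    expected = expected,
    timing_tally = timing_tally,
    mechanism_counts = c(
      incident = sum(true_cancers$mechanism == "incident"),
      captured = sum(captured & true_cancers$mechanism == "incident"),
      miscode = sum(true_cancers$mechanism == "miscode_true"),
      prevalent_fp = sum(admissions$mechanism == "prevalent_fp"),
      noise_fp = sum(admissions$mechanism == "noise_fp"),
      extra_admissions = sum(admissions$mechanism == "extra"),
      clamped = sum(admissions$clamped)
    )
  )
}

#' Summarize the truth ledger
#'
#' Returns the planted-mechanism counts and the expected per-group
#' TP/FP/FN cross-classification absent linkage noise. The expected counts
#' are the oracle for end-to-end pipeline tests: when linkage noise is off
#' the analysis must recover them exactly.
#'
#' @param ledger the `ledger` component of a [simulate_cohort()] result.
#' @return list with `expected` (per-group data.frame with an `"any"` total
#'   row), `mechanism_counts` and `timing_tally`.
#' @export
truth_summary <- function(ledger) {
  e <- ledger$expected
  any_row <- data.frame(group = "any", tp = sum(e$tp), fp = sum(e$fp),
                        fn = sum(e$fn), stringsAsFactors = FALSE)
  list(expected = rbind(e, any_row),
       mechanism_counts = ledger$mechanism_counts,
       timing_tally = ledger$timing_tally)
}
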