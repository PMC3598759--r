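# Cross-classification of hospital-index against registry cases and all
# derived reporting characteristics. Units throughout are (maternity x
# clinical group) pairs; the "any" row is the element-wise sum over the 13
# groups, so a maternity with two primary cancers contributes two units.

#' Cross-classify index hospital cases against registry cases
#'
#' Builds the per-group 2x2 confusion counts on (maternity, group) units:
#' `tp` pairs in both sources, `fp` hospital-only, `fn` registry-only, and
#' `tn = n_maternities - tp - fp - fn` (the negatives for a group are all
#' maternities without that group's cancer in either source). The `"any"`
#' row is the column-wise sum over groups.
#'
#' @param index_cases,registry_cases case data.frames from
#'   [hospital_index_cases()] and [registry_cases()].
#' @param n_maternities total number of maternities in the cohort.
#' @param groups group universe; defaults to [clinical_groups()].
#' @return data.frame with columns `group`, `tp`, `fp`, `fn`, `tn`; 13 group
#'   rows plus `"any"`.
#' @export
cross_classify <- function(index_cases, registry_cases, n_maternities,
                           groups = clinical_groups()) {
  stopifnot(length(n_maternities) == 1L, n_maternities >= 0)
  ikey <- paste(index_cases$maternity_id, index_cases$group, sep = "\r")
  rkey <- paste(registry_cases$maternity_id, registry_cases$group, sep = "\r")
  if (anyDuplicated(ikey)) stop("index cases not unique on (maternity, group)",
                                call. = FALSE)
  if (anyDuplicated(rkey)) stop("registry cases not unique on (maternity, group)",
                                call. = FALSE)
  n_seen <- length(unique(c(index_cases$maternity_id,
                            registry_cases$maternity_id)))
  if (n_seen > n_maternities) {
    stop(sprintf("n_maternities (%d) smaller than the %d distinct maternities in the case sets",
                 n_maternities, n_seen), call. = FALSE)
  }
  out <- data.frame(group = groups, tp = 0L, fp = 0L, fn = 0L, tn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    g <- groups[i]
    ig <- ikey[index_cases$group == g]
    rg <- rkey[registry_cases$group == g]
    tp <- length(intersect(ig, rg))
    fp <- length(ig) - tp
    fn <- length(rg) - tp
    if (tp + fp + fn > n_maternities) {
      stop(sprintf("n_maternities (%d) smaller than tp+fp+fn (%d) for group %s",
                   n_maternities, tp + fp + fn, g), call. = FALSE)
    }
    out[i, c("tp", "fp", "fn", "tn")] <-
      c(tp, fp, fn, n_maternities - tp - fp - fn)
  }
  any_row <- data.frame(group = "any", tp = sum(out$tp), fp = sum(out$fp),
                        fn = sum(out$fn), tn = sum(out$tn),
                        stringsAsFactors = FALSE)
  rbind(out, any_row)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Computes the exact interval for a binomial proportion from the Beta
#' quantile closed form: with `a = 1 - level`,
#' `low = qbeta(a/2, x, n - x + 1)` (0 when `x = 0`) and
#' `high = qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes (vectorized).
#' @param n number of trials.
#' @param level confidence level in (0, 1); default 0.95.
#' @return matrix with columns `low`, `high`.
#' @examples
#' proportion_ci(6, 6)    # lower bound 0.025^(1/6)
#' proportion_ci(115, 319)
#' @export
proportion_ci <- function(x, n, level = 0.95) {
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    stop("level must be a single value in (0, 1)", call. = FALSE)
  }
  k <- max(length(x), length(n))
  x <- rep_len(as.numeric(x), k)
  n <- rep_len(as.numeric(n), k)
  if (any(is.na(x) | is.na(n)) || any(n < 1) || any(x < 0) || any(x > n) ||
      any(x != floor(x)) || any(n != floor(n))) {
    stop("invalid binomial counts: need integer 0 <= x <= n, n >= 1",
         call. = FALSE)
  }
  a <- 1 - level
  low <- ifelse(x == 0, 0, stats::qbeta(a / 2, x, n - x + 1))
  high <- ifelse(x == n, 1, stats::qbeta(1 - a / 2, x + 1, n - x))
  cbind(low = low, high = high)
}

#' Reporting characteristics from 2x2 counts
#'
#' Computes sensitivity `tp/(tp+fn)`, positive predictive value `tp/(tp+fp)`,
#' specificity `tn/(tn+fp)` and negative predictive value `tn/(tn+fn)`, each
#' with its exact binomial interval on its own numerator and denominator.
#' Metrics with a zero denominator are undefined and returned as `NA`
#' (flagged in the `undefined` column), never silently 0.
#'
#' @param counts data.frame from [cross_classify()] (columns `group`, `tp`,
#'   `fp`, `fn`, `tn`).
#' @param level confidence level.
#' @return data.frame with, per metric `m` in sensitivity/ppv/specificity/
#'   npv, columns `m`, `m_low`, `m_high` (proportions in `[0,1]`), plus
#'   `group` and `undefined` (comma-separated names of undefined metrics).
#' @export
reporting_characteristics <- function(counts, level = 0.95) {
  one <- function(num, den) {
    if (den == 0L) return(c(NA_real_, NA_real_, NA_real_))
    ci <- proportion_ci(num, den, level)
    c(num / den, ci[1L, "low"], ci[1L, "high"])
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    tp <- counts$tp[i]; fp <- counts$fp[i]
    fn <- counts$fn[i]; tn <- counts$tn[i]
    v <- c(one(tp, tp + fn), one(tp, tp + fp), one(tn, tn + fp), one(tn, tn + fn))
    und <- c("sensitivity", "ppv", "specificity", "npv")[
      c(tp + fn, tp + fp, tn + fp, tn + fn) == 0L]
    list(v = v, und = paste(und, collapse = ","))
  })
  v <- do.call(rbind, lapply(res, `[[`, "v"))
  colnames(v) <- c("sensitivity", "sensitivity_low", "sensitivity_high",
                   "ppv", "ppv_low", "ppv_high",
                   "specificity", "specificity_low", "specificity_high",
                   "npv", "npv_low", "npv_high")
  out <- cbind(data.frame(group = counts$group, stringsAsFactors = FALSE),
               as.data.frame(v))
  out$undefined <- vapply(res, `[[`, character(1), "und")
  out
}

#' Incidence rates and incidence rate ratios
#'
#' Converts per-source case counts to crude incidence per 100,000 maternities
#' and forms, for each hospital source, the ratio of its rate to the registry
#' rate (IRR). Rates and IRRs are computed on unrounded values; rounding to
#' one decimal happens only at the presentation layer.
#'
#' @param counts data.frame with columns `group`, `registry_n`,
#'   `hospital_all_n`, `hospital_index_n`.
#' @param n_maternities cohort size (> 0).
#' @return data.frame with per-group counts, `*_rate` per 100,000, and
#'   `irr_all`, `irr_index` (NA where the registry count is 0).
#' @export
rates_and_irr <- function(counts, n_maternities) {
  stopifnot(n_maternities > 0)
  r <- function(n) 1e5 * n / n_maternities
  out <- counts
  out$registry_rate <- r(counts$registry_n)
  out$hospital_all_rate <- r(counts$hospital_all_n)
  out$hospital_index_rate <- r(counts$hospital_index_n)
  out$irr_all <- ifelse(counts$registry_n > 0,
                        out$hospital_all_rate / out$registry_rate, NA_real_)
  out$irr_index <- ifelse(counts$registry_n > 0,
                          out$hospital_index_rate / out$registry_rate, NA_real_)
  out
}

#' Adjudicate false-positive hospital cases
#'
#' Labels each false positive (hospital-index case without a matching
#' incident registry case) as:
#' \describe{
#'   \item{prevalent}{the woman has a registry notification of the same
#'     clinical group first notified before the exposure window start —
#'     an admission for a pre-existing cancer, found by registry lookback;}
#'   \item{misclassified_type}{otherwise, the same maternity has an incident
#'     registry cancer of a different group — the admission's cancer type was
#'     coded inconsistently;}
#'   \item{unexplained}{neither.}
#' }
#' Precedence is prevalent over misclassified_type.
#'
#' @param fp_cases data.frame of false-positive index cases (`maternity_id`,
#'   `woman_id`, `group`).
#' @param registry full registry table including pre-window notification
#'   history.
#' @param registry_case_set the incident registry case set from
#'   [registry_cases()].
#' @param windows window table.
#' @return list with `cases` (the input plus a `category` column) and
#'   `counts` (per-category totals, summing to the FP count).
#' @export
adjudicate_fp <- function(fp_cases, registry, registry_case_set, windows) {
  n <- nrow(fp_cases)
  category <- character(n)
  wstart <- windows$start_date[match(fp_cases$maternity_id, windows$maternity_id)]
  hist_key <- paste(registry$woman_id, registry$group, sep = "\r")
  for (i in seq_len(n)) {
    hk <- paste(fp_cases$woman_id[i], fp_cases$group[i], sep = "\r")
    rows <- which(hist_key == hk)
    prevalent <- length(rows) > 0L &&
      any(registry$first_notification_date[rows] < wstart[i])
    if (prevalent) {
      category[i] <- "prevalent"
    } else {
      other <- registry_case_set$maternity_id == fp_cases$maternity_id[i] &
        registry_case_set$group != fp_cases$group[i]
      category[i] <- if (any(other)) "misclassified_type" else "unexplained"
    }
  }
  cases <- fp_cases
  cases$category <- category
  counts <- c(prevalent = sum(category == "prevalent"),
              misclassified_type = sum(category == "misclassified_type"),
              unexplained = sum(category == "unexplained"))
  list(cases = cases, counts = counts)
}

#' Admission-versus-registration timing distribution
#'
#' Among true positives, bins the calendar-month difference between the
#' registry diagnosis date and the index admission date (registry month minus
#' admission month): 0 months is `same_month`, 1-2 `prior_1_2`, 3-5
#' `prior_3_5`, 6 or more `prior_6_plus`; a negative difference (admission
#' after registration) is `after_registration`.
#'
#' @param admission_date,registry_date equal-length `Date` vectors for the
#'   true-positive cases.
#' @return list with `counts` and `proportions` over the five bins
#'   (proportions sum to 1; all zero counts when there are no true
#'   positives).
#' @export
timing_distribution <- function(admission_date, registry_date) {
  stopifnot(length(admission_date) == length(registry_date))
  bins <- c("same_month", "prior_1_2", "prior_3_5", "prior_6_plus",
            "after_registration")
  counts <- stats::setNames(integer(5), bins)
  if (length(admission_date) > 0L) {
    d <- month_diff(as.Date(registry_date), as.Date(admission_date))
    counts["same_month"] <- sum(d == 0L)
    counts["prior_1_2"] <- sum(d >= 1L & d <= 2L)
    counts["prior_3_5"] <- sum(d >= 3L & d <= 5L)
    counts["prior_6_plus"] <- sum(d >= 6L)
    counts["after_registration"] <- sum(d < 0L)
  }
  total <- sum(counts)
  list(counts = counts,
       proportions = if (total > 0) counts / total else counts * 0)
}
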