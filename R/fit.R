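#' Validate hospital ascertainment of pregnancy-associated cancer
#'
#' The package's central fitting function. Given the three linked record
#' collections — maternities, hospital admissions and registry notifications
#' — it builds exposure windows, constructs the registry gold-standard,
#' hospital-index and all-hospitalisation case sets, cross-classifies index
#' cases against the registry on (maternity, clinical group) units, and
#' computes sensitivity, specificity, PPV and NPV with exact binomial
#' confidence intervals, crude incidence rates per 100,000 maternities with
#' incidence rate ratios, false-positive adjudication (prevalent cancer
#' versus miscoded type versus unexplained) and the admission-versus-
#' registration timing distribution among true positives.
#'
#' Unmatched woman ids in the hospital or registry tables (women without a
#' maternity) simply never attribute to a window and are ignored. The
#' analysis is fully deterministic.
#'
#' @param maternities,hospital,registry data.frames (or file paths) in the
#'   formats of [read_maternities()], [read_hospital()], [read_registry()].
#' @param map a `code_map`; defaults to [default_code_map()].
#' @param conf_level confidence level for all intervals (default 0.95).
#' @param rule window attribution rule, `"earliest"` (default) or `"all"`.
#' @return an object of class `pac_validation`: a list with components
#'   `n_maternities`, `windows`, `cases` (list of the three case sets),
#'   `counts` (2x2 table per group + "any"), `estimates` (reporting
#'   characteristics with CIs), `rates` (rates and IRRs per group + "any"),
#'   `fp` (adjudication), `timing` (month-bin distribution), `conf_level`,
#'   and `call`.
#' @examples
#' dir <- system.file("extdata", "example", package = "pacvalid")
#' fit <- pac_validation(file.path(dir, "maternities.csv"),
#'                       file.path(dir, "hospital.csv"),
#'                       file.path(dir, "registry.csv"))
#' fit
#' coef(fit)["any", ]
#' @export
pac_validation <- function(maternities, hospital, registry,
                           map = default_code_map(), conf_level = 0.95,
                           rule = c("earliest", "all")) {
  rule <- match.arg(rule)
  if (is.character(maternities) && length(maternities) == 1L)
    maternities <- read_maternities(maternities)
  if (is.character(hospital) && length(hospital) == 1L)
    hospital <- read_hospital(hospital)
  if (is.character(registry) && length(registry) == 1L)
    registry <- read_registry(registry)

  windows <- make_window(maternities)
  n_mat <- nrow(windows)

  reg <- registry_cases(registry, windows, rule = rule)
  idx <- hospital_index_cases(hospital, windows, map, rule = rule)
  all_h <- hospital_all_cases(hospital, windows, map, rule = rule)

  counts <- cross_classify(idx, reg, n_mat)
  estimates <- reporting_characteristics(counts, conf_level)

  tab <- function(cases) {
    n <- vapply(clinical_groups(), function(g) sum(cases$group == g), integer(1))
    c(n, any = sum(n))
  }
  src_counts <- data.frame(
    group = c(clinical_groups(), "any"),
    registry_n = tab(reg),
    hospital_all_n = tab(all_h),
    hospital_index_n = tab(idx),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rates <- rates_and_irr(src_counts, n_mat)

  ikey <- paste(idx$maternity_id, idx$group, sep = "\r")
  rkey <- paste(reg$maternity_id, reg$group, sep = "\r")
  fp_cases <- idx[!(ikey %in% rkey), c("maternity_id", "woman_id", "group",
                                       "event_date"), drop = FALSE]
  fp <- adjudicate_fp(fp_cases, registry, reg, windows)

  tp_idx <- idx[ikey %in% rkey, , drop = FALSE]
  mreg <- match(paste(tp_idx$maternity_id, tp_idx$group, sep = "\r"), rkey)
  timing <- timing_distribution(tp_idx$event_date, reg$event_date[mreg])

  structure(
    list(n_maternities = n_mat,
         windows = windows,
         cases = list(registry = reg, hospital_index = idx, hospital_all = all_h),
         counts = counts,
         estimates = estimates,
         rates = rates,
         fp = fp,
         timing = timing,
         conf_level = conf_level,
         rule = rule,
         call = match.call()),
    class = "pac_validation"
  )
}

#' @export
print.pac_validation <- function(x, ...) {
  a <- x$counts[x$counts$group == "any", ]
  e <- x$estimates[x$estimates$group == "any", ]
  cat("Hospital-vs-registry validation of pregnancy-associated cancer\n")
  cat(sprintf("  %s maternities; cases: registry %d, hospital index %d, hospital all %d\n",
              format(x$n_maternities, big.mark = ","),
              a$tp + a$fn, a$tp + a$fp,
              x$rates$hospital_all_n[x$rates$group == "any"]))
  cat(sprintf("  overall TP %d, FP %d, FN %d\n", a$tp, a$fp, a$fn))
  cat(sprintf("  sensitivity %.1f%% [%.1f, %.1f], PPV %.1f%% [%.1f, %.1f] (%.0f%% exact CI)\n",
              100 * e$sensitivity, 100 * e$sensitivity_low, 100 * e$sensitivity_high,
              100 * e$ppv, 100 * e$ppv_low, 100 * e$ppv_high,
              100 * x$conf_level))
  r <- x$rates[x$rates$group == "any", ]
  cat(sprintf("  registry incidence %.1f/100,000; IRR %.1f (all), %.1f (index)\n",
              r$registry_rate, r$irr_all, r$irr_index))
  cat("Use summary() for per-group tables.\n")
  invisible(x)
}

#' @export
summary.pac_validation <- function(object, ...) {
  structure(list(fit = object, tables = render_tables(object)),
            class = "summary.pac_validation")
}

#' @export
print.summary.pac_validation <- function(x, ...) {
  cat("Incidence of pregnancy-associated cancer by data source\n")
  cat(paste(x$tables$rates_text, collapse = "\n"), "\n\n")
  cat("Reporting characteristics of hospital-index ascertainment\n")
  cat(paste(x$tables$validation_text, collapse = "\n"), "\n\n")
  fpc <- x$fit$fp$counts
  tot <- sum(fpc)
  if (tot > 0) {
    cat(sprintf("False positives (n = %d): %d prevalent (%.1f%%), %d misclassified type (%.1f%%), %d unexplained\n",
                tot, fpc["prevalent"], 100 * fpc["prevalent"] / tot,
                fpc["misclassified_type"], 100 * fpc["misclassified_type"] / tot,
                fpc["unexplained"]))
  }
  tm <- x$fit$timing$proportions
  if (sum(x$fit$timing$counts) > 0) {
    cat(sprintf("Timing among true positives: %.0f%% same month, %.0f%% 1-2 months prior, %.0f%% 3-5, %.0f%% >= 6, %.0f%% after registration\n",
                100 * tm["same_month"], 100 * tm["prior_1_2"],
                100 * tm["prior_3_5"], 100 * tm["prior_6_plus"],
                100 * tm["after_registration"]))
  }
  invisible(x)
}

#' Extract point estimates from a validation fit
#'
#' @param object a `pac_validation` fit.
#' @param ... unused.
#' @return numeric matrix (rows: 13 groups + "any"; columns: sensitivity,
#'   ppv, specificity, npv), proportions in `[0, 1]`; `NA` marks undefined
#'   metrics.
#' @export
coef.pac_validation <- function(object, ...) {
  e <- object$estimates
  m <- as.matrix(e[, c("sensitivity", "ppv", "specificity", "npv")])
  rownames(m) <- e$group
  m
}

#' Confidence intervals for a validation fit
#'
#' @param object a `pac_validation` fit.
#' @param parm metric name(s): any of `"sensitivity"`, `"ppv"`,
#'   `"specificity"`, `"npv"`; default all.
#' @param level ignored (intervals are computed at the fit's `conf_level`).
#' @param ... unused.
#' @return numeric matrix of interval bounds, rows `group:metric`.
#' @export
confint.pac_validation <- function(object, parm = c("sensitivity", "ppv",
                                                    "specificity", "npv"),
                                   level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  e <- object$estimates
  out <- do.call(rbind, lapply(parm, function(p) {
    m <- cbind(e[[paste0(p, "_low")]], e[[paste0(p, "_high")]])
    rownames(m) <- paste(e$group, p, sep = ":")
    m
  }))
  colnames(out) <- c("low", "high")
  out
}

#' Forest-style plot of per-group sensitivity and PPV
#'
#' Draws point estimates and exact confidence intervals for sensitivity and
#' PPV per clinical group (base graphics).
#'
#' @param x a `pac_validation` fit.
#' @param metrics which metrics to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pac_validation <- function(x, metrics = c("sensitivity", "ppv"), ...) {
  e <- x$estimates[x$estimates$group != "any", ]
  ng <- nrow(e)
  k <- length(metrics)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0.5, ng + 0.5),
                 yaxt = "n", xlab = "proportion", ylab = "",
                 main = "Hospital ascertainment by clinical group", ...)
  graphics::axis(2, at = ng:1, labels = e$group, las = 1, cex.axis = 0.7)
  cols <- c("black", "grey50")[seq_len(k)]
  for (j in seq_len(k)) {
    m <- metrics[j]
    off <- (j - (k + 1) / 2) * 0.2
    y <- ng:1 + off
    graphics::segments(e[[paste0(m, "_low")]], y, e[[paste0(m, "_high")]], y,
                       col = cols[j])
    graphics::points(e[[m]], y, pch = 16, col = cols[j])
  }
  graphics::legend("bottomleft", legend = metrics, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}
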