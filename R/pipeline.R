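# End-to-end pipeline: read the three collections, fit the validation, and
# write delimited tables, a machine-readable JSON summary, and a run
# manifest. The analysis stage is deterministic; all randomness lives in the
# generator.

#' Run the full validation pipeline
#'
#' Reads the maternity, hospital and registry files, fits
#' [pac_validation()], and writes to `out_dir`: `rates.tsv` (per-group
#' incidence rates and IRRs by source), `validation.tsv` (per-group 2x2
#' counts and reporting characteristics with bracketed CIs),
#' `adjudication.tsv`, `timing.tsv`, `summary.json` (all counts, estimates,
#' CIs, adjudication, timing and the configuration used; byte-deterministic
#' for identical inputs) and `manifest.json` (input digests, seed, package
#' version, timestamp). Input files are never modified.
#'
#' @param maternity_file,hospital_file,registry_file input file paths.
#' @param out_dir output directory (created if needed).
#' @param map a `code_map` (or path to a YAML code map).
#' @param conf_level confidence level.
#' @param rule window attribution rule.
#' @param seed optional integer recorded in the manifest (the analysis draws
#'   no random numbers; the seed documents upstream generation).
#' @return the `pac_validation` fit, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(maternity_file, hospital_file, registry_file,
                         out_dir, map = default_code_map(), conf_level = 0.95,
                         rule = "earliest", seed = NULL) {
  if (is.character(map)) map <- read_code_map(map)
  fit <- pac_validation(maternity_file, hospital_file, registry_file,
                        map = map, conf_level = conf_level, rule = rule)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- render_tables(fit)
  writeLines(tables$rates_text, file.path(out_dir, "rates.tsv"))
  writeLines(tables$validation_text, file.path(out_dir, "validation.tsv"))

  adj <- data.frame(category = names(fit$fp$counts),
                    n = as.integer(fit$fp$counts),
                    pct = ifelse(sum(fit$fp$counts) > 0,
                                 round_half_up(100 * fit$fp$counts /
                                                 sum(fit$fp$counts), 1), 0))
  utils::write.table(adj, file.path(out_dir, "adjudication.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tim <- data.frame(bin = names(fit$timing$counts),
                    n = as.integer(fit$timing$counts),
                    proportion = as.numeric(fit$timing$proportions))
  utils::write.table(tim, file.path(out_dir, "timing.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  summary_obj <- pipeline_summary(fit, seed)
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "pacvalid",
    version = as.character(utils::packageVersion("pacvalid")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    conf_level = conf_level,
    rule = rule,
    inputs = list(
      maternities = unname(tools::md5sum(maternity_file)),
      hospital = unname(tools::md5sum(hospital_file)),
      registry = unname(tools::md5sum(registry_file))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

pipeline_summary <- function(fit, seed = NULL) {
  list(
    n_maternities = fit$n_maternities,
    conf_level = fit$conf_level,
    rule = fit$rule,
    seed = seed,
    counts = fit$counts,
    source_counts = fit$rates[, c("group", "registry_n", "hospital_all_n",
                                  "hospital_index_n")],
    rates = fit$rates[, c("group", "registry_rate", "hospital_all_rate",
                          "hospital_index_rate", "irr_all", "irr_index")],
    estimates = fit$estimates,
    fp_adjudication = as.list(fit$fp$counts),
    timing = list(counts = as.list(fit$timing$counts),
                  proportions = as.list(fit$timing$proportions))
  )
}

#' Render human-readable result tables
#'
#' Formats a fit as two delimited text tables mirroring the conventional
#' presentation: per-group incidence (counts, percent of column total, crude
#' rate per 100,000 maternities, and IRR against the registry for each
#' hospital source) and per-group reporting characteristics (TP/FP/FN,
#' sensitivity and PPV percentages with exact CIs in bracket notation).
#' Percentages and rates are rounded half-up to one decimal at this layer
#' only; undefined quantities render as `"undef"`.
#'
#' @param fit a `pac_validation` object.
#' @return list with `rates` and `validation` data.frames and their
#'   tab-delimited text renderings `rates_text`, `validation_text`
#'   (character vectors, one element per line, parseable with
#'   [utils::read.delim()]).
#' @export
render_tables <- function(fit) {
  fmt1 <- function(x) ifelse(is.na(x), "undef",
                             formatC(round_half_up(x, 1), format = "f",
                                     digits = 1))
  r <- fit$rates
  pct_of <- function(n) {
    tot <- n[r$group == "any"]
    if (length(tot) == 1L && tot > 0) 100 * n / tot
    else rep(NA_real_, length(n))
  }
  rates <- data.frame(
    group = r$group,
    registry_n = r$registry_n,
    registry_pct = fmt1(pct_of(r$registry_n)),
    registry_rate = fmt1(r$registry_rate),
    all_n = r$hospital_all_n,
    all_pct = fmt1(pct_of(r$hospital_all_n)),
    all_rate = fmt1(r$hospital_all_rate),
    all_irr = fmt1(r$irr_all),
    index_n = r$hospital_index_n,
    index_pct = fmt1(pct_of(r$hospital_index_n)),
    index_rate = fmt1(r$hospital_index_rate),
    index_irr = fmt1(r$irr_index),
    stringsAsFactors = FALSE
  )
  e <- fit$estimates
  cts <- fit$counts
  ci <- function(lo, hi) ifelse(is.na(lo), "undef",
                                paste0("[", fmt1(100 * lo), ",",
                                       fmt1(100 * hi), "]"))
  validation <- data.frame(
    group = cts$group, tp = cts$tp, fp = cts$fp, fn = cts$fn,
    sensitivity = fmt1(100 * e$sensitivity),
    sensitivity_ci = ci(e$sensitivity_low, e$sensitivity_high),
    ppv = fmt1(100 * e$ppv),
    ppv_ci = ci(e$ppv_low, e$ppv_high),
    stringsAsFactors = FALSE
  )
  to_text <- function(df) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1L, function(row) paste(row, collapse = "\t")))
  }
  list(rates = rates, validation = validation,
       rates_text = to_text(rates), validation_text = to_text(validation))
}
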