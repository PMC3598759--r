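#' Clinical cancer groups
#'
#' The 13 clinical groupings used to tabulate pregnancy-associated cancers.
#' Group order follows the conventional registry presentation (descending
#' registry frequency).
#'
#' @return character vector of the 13 group names.
#' @export
clinical_groups <- function() {
  c("melanoma", "breast", "thyroid_endocrine", "gynaecological",
    "lymphohaematopoeitic", "colorectal", "neurological", "bone_connective",
    "head_neck", "upper_gi", "respiratory", "ill_defined_unknown",
    "urogenital")
}

#' Default ICD-10 code-to-group mapping
#'
#' Maps malignant neoplasm codes C00-C96 to the 13 clinical groups along
#' ICD-10 chapter blocks, with C77-C79 treated as secondary/metastatic sites
#' and C44 (non-melanoma skin, not registered by population cancer
#' registries) out of scope. Stems unused by ICD-10 inside the eligible range
#' (C27-C29, C35-C36, C42, C59) are folded into the adjacent block so the
#' mapping covers the whole range; these stems never occur in coded data.
#'
#' The mapping is a documented approximation of registry clinical groupings
#' (which are not published at code level) and can be replaced wholesale via
#' [read_code_map()].
#'
#' @return an object of class `code_map`: a list with `groups` (data.frame of
#'   `start`, `end`, `group` numeric stem ranges), `secondary` (numeric stem
#'   range), and `eligible` (the inclusive candidate range, C00-C96).
#' @export
default_code_map <- function() {
  groups <- data.frame(
    start = c( 0L, 15L, 18L, 22L, 30L, 33L, 40L, 43L, 45L, 50L, 51L,
              60L, 69L, 73L, 76L, 80L, 81L),
    end   = c(14L, 17L, 21L, 29L, 32L, 39L, 42L, 43L, 49L, 50L, 59L,
              68L, 72L, 75L, 76L, 80L, 96L),
    group = c("head_neck", "upper_gi", "colorectal", "upper_gi", "head_neck",
              "respiratory", "bone_connective", "melanoma", "bone_connective",
              "breast", "gynaecological", "urogenital", "neurological",
              "thyroid_endocrine", "ill_defined_unknown",
              "ill_defined_unknown", "lymphohaematopoeitic"),
    stringsAsFactors = FALSE
  )
  new_code_map(groups, secondary = c(77L, 79L), out_of_scope = 44L)
}

new_code_map <- function(groups, secondary, out_of_scope = integer(0)) {
  stopifnot(is.data.frame(groups), all(c("start", "end", "group") %in% names(groups)))
  groups <- groups[order(groups$start), , drop = FALSE]
  bad <- setdiff(unique(groups$group), clinical_groups())
  if (length(bad) > 0L) {
    stop("unknown clinical group(s) in code map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map <- structure(
    list(groups = groups,
         secondary = as.integer(secondary),
         out_of_scope = as.integer(out_of_scope),
         eligible = c(0L, 96L)),
    class = "code_map"
  )
  validate_code_map(map)
  map
}

# Ranges must not overlap each other, the secondary block, or the explicit
# out-of-scope stems, and together they must cover the eligible range.
validate_code_map <- function(map) {
  covered <- integer(0)
  for (i in seq_len(nrow(map$groups))) {
    covered <- c(covered, seq(map$groups$start[i], map$groups$end[i]))
  }
  sec <- seq(map$secondary[1L], map$secondary[2L])
  all_claimed <- c(covered, sec, map$out_of_scope)
  if (anyDuplicated(all_claimed)) {
    stop("code map ranges overlap", call. = FALSE)
  }
  want <- seq(map$eligible[1L], map$eligible[2L])
  if (!setequal(all_claimed, want)) {
    stop("code map does not cover the eligible range C00-C96", call. = FALSE)
  }
  invisible(map)
}

#' @export
print.code_map <- function(x, ...) {
  cat("ICD-10 cancer code map: C00-C96 eligible,",
      sprintf("C%02d-C%02d secondary,", x$secondary[1L], x$secondary[2L]),
      if (length(x$out_of_scope) > 0L)
        paste0("C", sprintf("%02d", x$out_of_scope), " out of scope", collapse = ", ")
      else "",
      "\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# Normalize a diagnosis code to its 3-character alphanumeric stem
# ("c43.5", "C435" -> "C43"); errors on codes without letter + two digits.
code_stem <- function(code) {
  up <- toupper(gsub("[. ]", "", trimws(as.character(code))))
  ok <- grepl("^[A-Z][0-9]{2}", up)
  if (!all(ok | is.na(up))) {
    stop("malformed diagnosis code(s): ",
         paste(dQuote(as.character(code)[!ok & !is.na(up)][1:min(3, sum(!ok, na.rm = TRUE))]),
               collapse = ", "),
         " (expected a letter followed by two digits)", call. = FALSE)
  }
  substr(up, 1L, 3L)
}

#' Classify a diagnosis code
#'
#' Classifies ICD-10-style diagnosis codes as incident primary cancer
#' candidates (returning their clinical group), secondary/metastatic sites,
#' or out of scope. Only C00-C96 enter candidacy; in-situ and benign
#' neoplasms (D codes) and all non-neoplasm codes are out of scope, as are
#' explicit out-of-scope stems (C44 by default). Comparison ignores
#' dot-suffix subdivisions and case.
#'
#' @param code character vector of diagnosis codes (e.g. `"C43.5"`).
#' @param map a `code_map`, by default [default_code_map()].
#' @return character vector: the clinical group name for incident candidates,
#'   `"secondary"` for secondary sites, `"out_of_scope"` otherwise.
#' @examples
#' classify_code(c("C43.5", "C78.0", "D05.1", "O80"))
#' @export
classify_code <- function(code, map = default_code_map()) {
  if (length(code) == 0L) return(character(0))
  stem <- code_stem(code)
  out <- rep("out_of_scope", length(stem))
  isc <- !is.na(stem) & substr(stem, 1L, 1L) == "C"
  num <- suppressWarnings(as.integer(substr(stem, 2L, 3L)))
  inrange <- isc & !is.na(num) & num >= map$eligible[1L] & num <= map$eligible[2L]
  sec <- inrange & num >= map$secondary[1L] & num <= map$secondary[2L]
  out[sec] <- "secondary"
  cand <- inrange & !sec & !(num %in% map$out_of_scope)
  if (any(cand)) {
    idx <- findInterval(num[cand], map$groups$start)
    hit <- idx >= 1L & num[cand] <= map$groups$end[pmax(idx, 1L)]
    res <- rep("out_of_scope", sum(cand))
    res[hit] <- map$groups$group[idx[hit]]
    out[cand] <- res
  }
  out[is.na(stem)] <- NA_character_
  out
}

#' Assign a clinical group to a multi-code record
#'
#' Scans an ordered list of diagnosis codes (up to 22 fields per admission)
#' and returns the clinical group of the first incident-candidate code, or
#' `NA` if no code qualifies. Secondary and out-of-scope codes are skipped.
#'
#' @param codes character vector of 1-22 diagnosis codes in field order;
#'   empty strings and `NA` entries (blank-padded fields) are ignored.
#' @param map a `code_map`.
#' @return a single group name, or `NA_character_`.
#' @examples
#' record_group(c("O80", "C50.9"))
#' record_group(c("C18.2", "C50.9"))
#' @export
record_group <- function(codes, map = default_code_map()) {
  codes <- codes[!is.na(codes) & nzchar(trimws(codes))]
  if (length(codes) == 0L) {
    stop("record_group: empty diagnosis code list", call. = FALSE)
  }
  if (length(codes) > 22L) {
    stop("record_group: more than 22 diagnosis fields", call. = FALSE)
  }
  cls <- classify_code(codes, map)
  hit <- which(!cls %in% c("secondary", "out_of_scope"))
  if (length(hit) == 0L) NA_character_ else cls[hit[1L]]
}

# Vectorized record grouping over a character matrix (records x fields);
# returns the first incident-candidate group per row. Used by the
# ascertainment stage so 10^5-row cohorts stay fast.
record_group_matrix <- function(code_mat, map = default_code_map()) {
  stopifnot(is.matrix(code_mat))
  n <- nrow(code_mat)
  out <- rep(NA_character_, n)
  undecided <- rep(TRUE, n)
  for (j in seq_len(ncol(code_mat))) {
    if (!any(undecided)) break
    col <- code_mat[, j]
    live <- undecided & !is.na(col) & nzchar(trimws(col))
    if (!any(live)) next
    cls <- classify_code(col[live], map)
    isgrp <- !cls %in% c("secondary", "out_of_scope")
    rows <- which(live)[isgrp]
    out[rows] <- cls[isgrp]
    undecided[rows] <- FALSE
  }
  out
}

#' Read / write a code map
#'
#' Serializes the code-to-group mapping to a YAML file with entries
#' `groups:` (list of `{start, end, group}` stem ranges given as `Cnn`
#' strings), `secondary:` and `out_of_scope:`. The packaged default lives at
#' `system.file("extdata", "code_groups.yaml", package = "pacvalid")`.
#'
#' @param path file path.
#' @return `read_code_map()` returns a `code_map`; `write_code_map()` returns
#'   `path` invisibly.
#' @export
read_code_map <- function(path) {
  y <- yaml::read_yaml(path)
  g <- do.call(rbind, lapply(y$groups, function(e) {
    data.frame(start = stem_num(e$start), end = stem_num(e$end),
               group = e$group, stringsAsFactors = FALSE)
  }))
  new_code_map(g,
               secondary = vapply(y$secondary, stem_num, integer(1)),
               out_of_scope = vapply(y$out_of_scope %||% list(), stem_num, integer(1)))
}

stem_num <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  as.integer(substr(toupper(trimws(x)), 2L, 3L))
}

#' @rdname read_code_map
#' @param map a `code_map` to serialize.
#' @export
write_code_map <- function(map, path) {
  y <- list(
    groups = lapply(seq_len(nrow(map$groups)), function(i) {
      list(start = sprintf("C%02d", map$groups$start[i]),
           end = sprintf("C%02d", map$groups$end[i]),
           group = map$groups$group[i])
    }),
    secondary = sprintf("C%02d", map$secondary),
    out_of_scope = as.list(sprintf("C%02d", map$out_of_scope))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
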