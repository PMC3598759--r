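#' Reference validation counts, NSW 2001-2008 linked maternity cohort
#'
#' Per-group case counts from the published validation of hospital discharge
#' ascertainment of pregnancy-associated cancer in the New South Wales
#' 2001-2008 linked maternity population (679,736 maternities, 470,277
#' women): registry ("gold standard") case counts, hospital
#' all-hospitalisation and index-hospitalisation counts, and the
#' true-positive / false-positive / false-negative cross-classification of
#' index cases against the registry. These counts parameterize the default
#' synthetic generator configuration ([pac_config()]) and serve as reference
#' inputs for reproducing the derived statistics.
#'
#' Note: in the source tables the per-group TP+FP totals (746 overall) do
#' not equal the index-hospitalisation counts (770 overall); this is an
#' artefact of the source data. The pipeline itself always satisfies
#' tp + fp = index count.
#'
#' @return data.frame with columns `group`, `registry_n`, `hospital_all_n`,
#'   `hospital_index_n`, `tp`, `fp`, `fn`; attribute `n_maternities`
#'   (679,736) and `n_women` (470,277).
#' @export
nsw_reference_counts <- function() {
  df <- data.frame(
    group = clinical_groups(),
    registry_n       = c(322L, 218L, 133L, 94L, 87L, 35L, 22L, 19L, 14L, 18L, 7L, 11L, 8L),
    hospital_all_n   = c(168L, 491L, 198L, 161L, 340L, 44L, 57L, 64L, 13L, 124L, 17L, 22L, 19L),
    hospital_index_n = c(142L, 152L, 119L, 81L, 110L, 22L, 24L, 25L, 11L, 52L, 9L, 12L, 11L),
    tp = c(115L, 134L, 103L, 70L, 62L, 18L, 20L, 16L, 9L, 15L, 6L, 4L, 8L),
    fp = c(29L, 20L, 15L, 15L, 48L, 11L, 4L, 7L, 2L, 5L, 3L, 4L, 3L),
    fn = c(204L, 79L, 28L, 20L, 24L, 10L, 2L, 2L, 4L, 3L, 0L, 4L, 0L),
    stringsAsFactors = FALSE
  )
  attr(df, "n_maternities") <- 679736L
  attr(df, "n_women") <- 470277L
  # false-positive adjudication totals: 86 prevalent, 22 misclassified type
  attr(df, "fp_prevalent") <- 86L
  attr(df, "fp_misclassified") <- 22L
  df
}
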