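#' Published reference-cohort counts
#'
#' Counts reported by a published three-year follow-up of 61 double lung and
#' heart-lung transplant recipients, shipped with the package so that the
#' count-level machinery (operating characteristics, predictive ability,
#' patient-level BOS 0-p statistics) can be exercised and reproduced without
#' any synthesis:
#'
#' * `reference_test_counts()` — normal/abnormal test-result counts by current
#'   diagnostic status for six cut-offs, pooled over 6-36 months among the 58
#'   analysed recipients.
#' * `reference_prediction_counts()` — pre-diagnosis occasion counts over
#'   6-24 months for the FEV1, N2-slope and combined criteria.
#' * `reference_outcome_counts()` — patient-level BOS / BOS 0-p outcome
#'   counts, as a named integer vector.
#'
#' @return Tibbles (or a named vector, see above) of the packaged counts.
#' @export
reference_test_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_test_counts.tsv", package = "bosn2",
                mustWork = TRUE),
    comment = "#", show_col_types = FALSE
  )
}

#' @rdname reference_test_counts
#' @export
reference_prediction_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_prediction_counts.tsv", package = "bosn2",
                mustWork = TRUE),
    comment = "#", show_col_types = FALSE
  )
}

#' @rdname reference_test_counts
#' @export
reference_outcome_counts <- function() {
  df <- readr::read_tsv(
    system.file("extdata", "reference_outcome_counts.tsv", package = "bosn2",
                mustWork = TRUE),
    comment = "#", show_col_types = FALSE
  )
  setNames(as.integer(df$count), df$quantity)
}

#' Contingency counts from one row of the reference test-count table
#'
#' @param row One-row tibble (or list) with the count columns of
#'   [reference_test_counts()].
#' @return A [contingency_counts()] matrix.
#' @export
row_to_contingency <- function(row) {
  contingency_counts(
    row$nobos_normal, row$nobos_abnormal,
    row$bos_normal, row$bos_abnormal,
    row$bos0p_normal, row$bos0p_abnormal
  )
}
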