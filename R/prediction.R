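#' Criterion for the predictive-ability analysis
#'
#' One or more cut-off components; an occasion is abnormal only when *all*
#' components are abnormal (and is dropped from the pool when any component's
#' measurement is missing, since all tests must be evaluable simultaneously).
#'
#' @param ... [cutoff_spec()] objects, or a single list of them.
#' @return An object of class `prediction_criterion`.
#' @export
prediction_criterion <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1]], "cutoff_spec")) {
    comps <- comps[[1]]
  }
  if (length(comps) == 0L ||
      !all(vapply(comps, inherits, logical(1), "cutoff_spec"))) {
    config_error("a prediction criterion needs at least one cutoff_spec component")
  }
  structure(list(components = comps), class = "prediction_criterion")
}

#' Predictive-ability counts
#'
#' Container for the bespoke predictive-ability statistic: among abnormal test
#' results obtained while the patient was *not yet* diagnosed with BOS, the
#' percentage that precede a later BOS diagnosis. This is deliberately
#' different from a conventional positive predictive value, which would also
#' count abnormal results obtained after diagnosis.
#'
#' @param total_results Number of pooled pre-diagnosis measurement occasions.
#' @param total_abnormal Number of those that were abnormal.
#' @param abnormal_preceding_bos Number of abnormal occasions in patients
#'   later diagnosed with BOS.
#' @return An object of class `prediction_counts` with `predictive_value`
#'   (percent, rounded half-up; NA when no abnormal results).
#' @export
#' @examples
#' prediction_counts(259, 22, 12)$predictive_value # 55
prediction_counts <- function(total_results, total_abnormal,
                              abnormal_preceding_bos) {
  if (abnormal_preceding_bos > total_abnormal || total_abnormal > total_results ||
      min(total_results, total_abnormal, abnormal_preceding_bos) < 0) {
    config_error("counts must satisfy 0 <= preceding <= abnormal <= total")
  }
  pv <- if (total_abnormal > 0) {
    round_half_up(100 * abnormal_preceding_bos / total_abnormal)
  } else {
    NA_real_
  }
  structure(
    list(total_results = total_results, total_abnormal = total_abnormal,
         abnormal_preceding_bos = abnormal_preceding_bos,
         predictive_value = pv),
    class = "prediction_counts"
  )
}

#' @export
print.prediction_counts <- function(x, ...) {
  cat(sprintf(
    "<prediction_counts> %d results, %d abnormal, %d preceding BOS -> predictive value %s%%\n",
    x$total_results, x$total_abnormal, x$abnormal_preceding_bos,
    if (is.na(x$predictive_value)) "NA" else format(x$predictive_value)
  ))
  invisible(x)
}

# Per-occasion table for a criterion: one row per (patient, visit) inside the
# window at which the patient is not yet diagnosed with BOS and every
# component measurement is available, with its abnormality and whether a later
# BOS onset exists.
prediction_occasions <- function(normalized, staging, criterion,
                                 window = c(6, 24), exclude_patients = NULL) {
  if (!inherits(criterion, "prediction_criterion")) {
    config_error("`criterion` must be a prediction_criterion")
  }
  if (is.null(exclude_patients)) {
    exclude_patients <- staging$outcomes$patient_id[staging$outcomes$terminal_bos0p]
  }
  onset <- setNames(staging$outcomes$bos_onset, staging$outcomes$patient_id)

  comp_tables <- lapply(seq_along(criterion$components), function(i) {
    comp <- criterion$components[[i]]
    col <- if (comp$dimension == "pct_basal") "pct_baseline" else "pct_predicted"
    df <- dplyr::filter(
      normalized,
      .data$variable == comp$variable,
      .data$months_post_tx >= window[1], .data$months_post_tx <= window[2],
      !(.data$patient_id %in% exclude_patients)
    )
    if (col == "pct_baseline") df <- dplyr::filter(df, !.data$baseline_provisional)
    df <- dplyr::filter(df, !is.na(.data[[col]]))
    tibble::tibble(
      patient_id = df$patient_id, months_post_tx = df$months_post_tx,
      abnormal = is_abnormal(df[[col]], comp)
    )
  })
  occ <- comp_tables[[1]]
  names(occ)[3] <- "abnormal_1"
  if (length(comp_tables) > 1) {
    for (i in 2:length(comp_tables)) {
      tab <- comp_tables[[i]]
      names(tab)[3] <- paste0("abnormal_", i)
      occ <- dplyr::inner_join(occ, tab, by = c("patient_id", "months_post_tx"))
    }
  }
  occ$abnormal <- rowSums(!as.matrix(occ[grep("^abnormal_", names(occ))])) == 0
  occ$bos_onset <- unname(onset[occ$patient_id])
  # only occasions before diagnosis enter the pool
  occ <- occ[is.na(occ$bos_onset) | occ$months_post_tx < occ$bos_onset, ]
  occ$preceding_bos <- !is.na(occ$bos_onset) & occ$months_post_tx < occ$bos_onset
  occ[c("patient_id", "months_post_tx", "abnormal", "preceding_bos")]
}

#' Predictive ability of an abnormal test result
#'
#' Pools every measurement occasion inside the window at which the patient is
#' not yet diagnosed with BOS and every criterion component is available. An
#' occasion is abnormal when all components are abnormal; it precedes BOS when
#' the patient's onset exists and is strictly later than the occasion.
#' Patients ending follow-up in BOS 0-p with an unresolved outcome are
#' excluded.
#'
#' @param normalized Output of [normalize_cohort()].
#' @param staging Output of [stage_cohort()] on the same cohort.
#' @param criterion A [prediction_criterion()].
#' @param window Months interval of pooled occasions (default 6-24).
#' @param exclude_patients Patient ids to drop; defaults to terminal BOS 0-p
#'   patients.
#' @return A [prediction_counts()] object.
#' @export
predictive_ability <- function(normalized, staging, criterion,
                               window = c(6, 24), exclude_patients = NULL) {
  occ <- prediction_occasions(normalized, staging, criterion, window,
                              exclude_patients)
  pc <- prediction_counts(
    total_results = nrow(occ),
    total_abnormal = sum(occ$abnormal),
    abnormal_preceding_bos = sum(occ$abnormal & occ$preceding_bos)
  )
  if (pc$total_abnormal == 0L) {
    warn("no abnormal results in the pool; predictive value undefined")
  }
  pc
}

#' Abnormal occasions over time for a criterion
#'
#' Histogram of abnormal occasions keyed by scheduled visit month, split into
#' those preceding a later BOS diagnosis and the rest; the totals equal the
#' corresponding [predictive_ability()] counts.
#'
#' @inheritParams predictive_ability
#' @return A tibble with `months_post_tx`, `n_abnormal`, `n_preceding_bos`.
#' @export
combined_abnormal_timeline <- function(normalized, staging, criterion,
                                       window = c(6, 24),
                                       exclude_patients = NULL) {
  occ <- prediction_occasions(normalized, staging, criterion, window,
                              exclude_patients)
  occ <- occ[occ$abnormal, ]
  if (nrow(occ) == 0L) {
    return(tibble::tibble(months_post_tx = numeric(), n_abnormal = integer(),
                          n_preceding_bos = integer()))
  }
  grouped <- dplyr::group_by(occ, .data$months_post_tx)
  out <- dplyr::summarise(
    grouped,
    n_abnormal = dplyr::n(),
    n_preceding_bos = sum(.data$preceding_bos),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$months_post_tx)
}
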