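#' Read a long-format visit table
#'
#' Expects tab-separated text with columns `patient_id`, `sex`, `age_years`,
#' `height_cm`, `months_post_tx`, `variable`, `value`; `#` lines are comments.
#' Rows are sorted chronologically within patient and variable; duplicate
#' (patient, month, variable) rows are a validation error.
#'
#' @param path Path to the TSV file.
#' @return A visit tibble as produced by [generate_cohort()].
#' @export
read_visit_table <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("input file not found: %s", path))
  visits <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  needed <- c("patient_id", "sex", "age_years", "height_cm",
              "months_post_tx", "variable", "value")
  missing_cols <- setdiff(needed, names(visits))
  if (length(missing_cols) > 0) {
    validation_error(sprintf("%s lacks column(s): %s", path,
                             paste(missing_cols, collapse = ", ")))
  }
  key <- paste(visits$patient_id, visits$months_post_tx, visits$variable)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    validation_error(sprintf(
      "duplicate (patient, month, variable) row at line %d: %s",
      dup, key[dup]
    ))
  }
  if (nrow(visits) > 0 && any(is.na(visits$value) | visits$value <= 0)) {
    bad <- which(is.na(visits$value) | visits$value <= 0)[1]
    validation_error(sprintf("non-positive or missing value in row %d (column value)", bad))
  }
  dplyr::arrange(visits, .data$patient_id, .data$variable, .data$months_post_tx)
}

tsv_header <- function(seed = NULL, what = "") {
  c(
    sprintf("# bosn2 %s", what),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed))
  )
}

write_tsv_with_header <- function(df, path, seed = NULL, what = "") {
  writeLines(tsv_header(seed, what), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a synthetic cohort (visit table plus truth sidecar)
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "bos_cohort")) config_error("`cohort` must be a bos_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "visits.tsv")
  p2 <- file.path(dir, "truth.tsv")
  write_tsv_with_header(cohort$visits, p1, cohort$config$seed, "synthetic visit table")
  write_tsv_with_header(cohort$truth, p2, cohort$config$seed, "synthetic cohort truth sidecar")
  invisible(c(visits = p1, truth = p2))
}

# pooled stable-patient results of one variable/dimension inside the window;
# stable = never BOS and never staged BOS 0-p
stable_pool <- function(normalized, staging, variable,
                        dimension = c("pct_basal", "pct_pred"),
                        window = c(6, 36)) {
  dimension <- match.arg(dimension)
  stable_ids <- staging$outcomes$patient_id[
    is.na(staging$outcomes$bos_onset) & !staging$outcomes$ever_bos0p
  ]
  col <- if (dimension == "pct_basal") "pct_baseline" else "pct_predicted"
  df <- dplyr::filter(
    normalized,
    .data$variable == !!variable,
    .data$patient_id %in% stable_ids,
    .data$months_post_tx >= window[1], .data$months_post_tx <= window[2]
  )
  if (col == "pct_baseline") df <- dplyr::filter(df, !.data$baseline_provisional)
  df[[col]][!is.na(df[[col]])]
}

default_cutoff_plan <- function() {
  list(
    list(variable = "FEV1", dimension = "pct_basal", direction = "less",
         source = "fixed", value = 90),
    list(variable = "FVC", dimension = "pct_basal", direction = "less",
         source = "calibrated", value = NA_real_),
    list(variable = "N2_slope", dimension = "pct_basal", direction = "greater",
         source = "calibrated", value = NA_real_),
    list(variable = "FEV1", dimension = "pct_pred", direction = "less",
         source = "calibrated", value = NA_real_),
    list(variable = "FVC", dimension = "pct_pred", direction = "less",
         source = "calibrated", value = NA_real_),
    list(variable = "N2_slope", dimension = "pct_pred", direction = "greater",
         source = "calibrated", value = NA_real_)
  )
}

#' Run the whole analysis pipeline
#'
#' From a visit table (synthetic or user supplied) to the full report bundle:
#' normalised measurements, staged visits and patient outcomes, stage
#' prevalence per visit, calibrated cut-offs with their contingency counts and
#' operating characteristics, predictive-ability counts for the FEV1, N2-slope
#' and combined criteria with the abnormal-occasion histogram, patient-level
#' BOS 0-p predictor statistics, and a flat named summary of the headline
#' percentages. Fully deterministic given the seed in `config`.
#'
#' @param visits Long-format visit tibble; when NULL a synthetic cohort is
#'   generated from `config`.
#' @param config A [cohort_config()] used when `visits` is NULL (its seed is
#'   recorded in all outputs).
#' @param refset Reference-equation table.
#' @param rules Staging rules.
#' @param cutoff_plan List describing which cut-offs to fix or calibrate; see
#'   the default in the source.
#' @param target_specificity Calibration target, percent (default 95).
#' @param calibration_window,evaluation_window Months intervals for the cut-off
#'   calibration pool and the pooled contingency counts (default both 6-36).
#' @param prediction_window Months interval of the predictive-ability pool
#'   (default 6-24).
#' @param counterfactual_progressors Passed to [bos0p_predictor_stats()].
#' @param out_dir When non-NULL, all tables are also written there as TSV.
#' @return A list (class `bos_report`) with elements `cohort` (NULL for user
#'   data), `normalized`, `staging`, `stage_table`, `cutoffs`, `counts`,
#'   `characteristics`, `prediction`, `histogram`, `bos0p_stats`, `summary`.
#' @export
run_pipeline <- function(visits = NULL, config = cohort_config(),
                         refset = default_reference_set(),
                         rules = stage_rules(),
                         cutoff_plan = default_cutoff_plan(),
                         target_specificity = 95,
                         calibration_window = c(6, 36),
                         evaluation_window = c(6, 36),
                         prediction_window = c(6, 24),
                         counterfactual_progressors = 1,
                         out_dir = NULL) {
  cohort <- NULL
  if (is.null(visits)) {
    cohort <- generate_cohort(config)
    visits <- cohort$visits
  }
  normalized <- normalize_cohort(visits, refset)
  staging <- stage_cohort(normalized, rules)
  stage_table <- stage_prevalence(
    staging$staged,
    months_keep = sort(unique(staging$staged$months_post_tx[staging$staged$months_post_tx >= 6]))
  )

  cutoffs <- lapply(cutoff_plan, function(p) {
    if (identical(p$source, "fixed")) {
      cutoff_spec(p$variable, p$dimension, p$direction, p$value, "fixed")
    } else {
      pool <- stable_pool(normalized, staging, p$variable, p$dimension,
                          calibration_window)
      calibrate_cutoff(pool, p$direction, target_specificity,
                       variable = p$variable, dimension = p$dimension)
    }
  })
  names(cutoffs) <- vapply(cutoffs, function(co) {
    paste(co$variable, co$dimension, sep = "_")
  }, character(1))

  counts <- lapply(cutoffs, function(co) {
    tabulate_counts(normalized, staging, co, evaluation_window)
  })
  characteristics <- lapply(counts, operating_characteristics)

  fev1_cut <- cutoffs[["FEV1_pct_basal"]]
  n2_cut <- cutoffs[["N2_slope_pct_pred"]]
  criteria <- list(
    fev1 = prediction_criterion(fev1_cut),
    n2 = prediction_criterion(n2_cut),
    combined = prediction_criterion(fev1_cut, n2_cut)
  )
  prediction <- lapply(criteria, function(cr) {
    predictive_ability(normalized, staging, cr, prediction_window)
  })
  histogram <- combined_abnormal_timeline(normalized, staging,
                                          criteria$combined, prediction_window)
  bos0p_stats <- bos0p_predictor_stats(staging$outcomes,
                                       counterfactual_progressors)

  summary <- c(
    setNames(
      unlist(lapply(characteristics, function(oc) oc$rounded["specificity"])),
      paste0("specificity_", names(characteristics))
    ),
    setNames(
      unlist(lapply(characteristics, function(oc) oc$rounded["sensitivity_bos"])),
      paste0("sensitivity_bos_", names(characteristics))
    ),
    predictive_value_fev1 = prediction$fev1$predictive_value,
    predictive_value_n2 = prediction$n2$predictive_value,
    predictive_value_combined = prediction$combined$predictive_value,
    bos0p_sensitivity = bos0p_stats$sensitivity,
    bos0p_specificity = bos0p_stats$specificity,
    bos0p_ppv = bos0p_stats$ppv
  )

  bundle <- structure(
    list(cohort = cohort, normalized = normalized, staging = staging,
         stage_table = stage_table, cutoffs = cutoffs, counts = counts,
         characteristics = characteristics, prediction = prediction,
         histogram = histogram, bos0p_stats = bos0p_stats, summary = summary,
         seed = config$seed),
    class = "bos_report"
  )
  if (!is.null(out_dir)) write_tables(bundle, out_dir)
  bundle
}

#' Write a report bundle as TSV files
#'
#' Writes `staged.tsv`, `stage_prevalence.tsv`, `test_counts.tsv`,
#' `operating_characteristics.tsv`, `prediction.tsv`, `histogram.tsv` and
#' `summary.tsv` to `dir`, each with a `#` header recording the seed.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  if (!inherits(bundle, "bos_report")) config_error("`bundle` must be a bos_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- bundle$seed
  write_tsv_with_header(bundle$staging$staged, file.path(dir, "staged.tsv"),
                        seed, "staged visits")
  write_tsv_with_header(bundle$stage_table, file.path(dir, "stage_prevalence.tsv"),
                        seed, "patients per stage per visit")

  counts_df <- dplyr::bind_rows(lapply(names(bundle$counts), function(nm) {
    m <- bundle$counts[[nm]]
    co <- bundle$cutoffs[[nm]]
    tibble::tibble(
      variable = co$variable, dimension = co$dimension,
      direction = co$direction, cutoff = co$value, source = co$source,
      nobos_normal = m["NoBOS", "normal"], nobos_abnormal = m["NoBOS", "abnormal"],
      bos_normal = m["BOS", "normal"], bos_abnormal = m["BOS", "abnormal"],
      bos0p_normal = m["BOS0p", "normal"], bos0p_abnormal = m["BOS0p", "abnormal"]
    )
  }))
  write_tsv_with_header(counts_df, file.path(dir, "test_counts.tsv"),
                        seed, "normal/abnormal counts by diagnostic status")

  oc_df <- dplyr::bind_rows(lapply(names(bundle$characteristics), function(nm) {
    oc <- bundle$characteristics[[nm]]
    tibble::tibble(cutoff = nm, !!!as.list(oc$rounded))
  }))
  write_tsv_with_header(oc_df, file.path(dir, "operating_characteristics.tsv"),
                        seed, "operating characteristics")

  pred_df <- dplyr::bind_rows(lapply(names(bundle$prediction), function(nm) {
    pc <- bundle$prediction[[nm]]
    tibble::tibble(
      criterion = nm, total_results = pc$total_results,
      total_abnormal = pc$total_abnormal,
      abnormal_preceding_bos = pc$abnormal_preceding_bos,
      predictive_value = pc$predictive_value
    )
  }))
  write_tsv_with_header(pred_df, file.path(dir, "prediction.tsv"),
                        seed, "predictive ability")
  write_tsv_with_header(bundle$histogram, file.path(dir, "histogram.tsv"),
                        seed, "combined-criterion abnormal occasions over time")
  write_tsv_with_header(
    tibble::tibble(quantity = names(bundle$summary),
                   value = unname(bundle$summary)),
    file.path(dir, "summary.tsv"), seed, "headline statistics"
  )
  invisible(dir)
}

#' @export
print.bos_report <- function(x, ...) {
  cat("<bos_report>\n")
  print(tibble::tibble(quantity = names(x$summary), value = unname(x$summary)),
        n = length(x$summary))
  invisible(x)
}
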