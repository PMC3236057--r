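#' Cut-off specification
#'
#' @param variable Variable name (see [lung_function_variables()]).
#' @param dimension `"pct_basal"` (percent of the latest baseline) or
#'   `"pct_pred"` (percent of predicted normal).
#' @param direction `"less"` (abnormal if strictly below the cut-off) or
#'   `"greater"` (abnormal if strictly above).
#' @param value Cut-off value in percent.
#' @param source `"calibrated"` (from a stable-patient pool) or `"fixed"`
#'   (e.g. the FEV1 < 90% basal cut-off, which is the BOS 0-p definition
#'   itself and is therefore not calibrated).
#' @return An object of class `cutoff_spec`.
#' @export
cutoff_spec <- function(variable, dimension = c("pct_basal", "pct_pred"),
                        direction = c("less", "greater"), value,
                        source = c("fixed", "calibrated")) {
  dimension <- match.arg(dimension)
  direction <- match.arg(direction)
  source <- match.arg(source)
  stopifnot_scalar_number(value, "value")
  if (value <= 0) config_error("cut-off `value` must be > 0")
  structure(
    list(variable = variable, dimension = dimension, direction = direction,
         value = value, source = source),
    class = "cutoff_spec"
  )
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat(sprintf("<cutoff_spec> %s %s %s %.4g (%s)\n", x$variable, x$dimension,
              if (x$direction == "less") "<" else ">", x$value, x$source))
  invisible(x)
}

#' Classify measurements as abnormal under a cut-off
#'
#' Abnormality requires strict inequality beyond the cut-off, so borderline
#' values (equal to the cut-off) count as normal.
#'
#' @param values Numeric measurements (percent).
#' @param cutoff A [cutoff_spec()].
#' @return Logical vector.
#' @export
is_abnormal <- function(values, cutoff) {
  if (cutoff$direction == "less") values < cutoff$value else values > cutoff$value
}

#' Calibrate a cut-off to a target specificity on stable patients
#'
#' Chooses the cut-off as an order statistic of the pooled stable-patient
#' results: the `ceiling(target * n)`-th smallest value for
#' abnormal-if-greater (and symmetrically for abnormal-if-less), with
#' abnormality requiring strict inequality beyond it. This guarantees that,
#' reapplied to its own calibration pool, the cut-off yields specificity in
#' `[target, target + 100/n]` percent.
#'
#' @param stable_results Pooled measurements of stable patients within the
#'   calibration window.
#' @param direction `"less"` or `"greater"` (which tail is abnormal).
#' @param target_specificity Target specificity in percent (default 95).
#' @param variable,dimension Passed through to the returned [cutoff_spec()].
#' @return A [cutoff_spec()] with `source = "calibrated"`.
#' @export
#' @examples
#' calibrate_cutoff(1:100, "greater")$value # 95: exactly 5 of 100 abnormal
calibrate_cutoff <- function(stable_results, direction = c("less", "greater"),
                             target_specificity = 95,
                             variable = NA_character_,
                             dimension = c("pct_basal", "pct_pred")) {
  direction <- match.arg(direction)
  dimension <- match.arg(dimension)
  values <- stable_results[!is.na(stable_results)]
  n <- length(values)
  if (n == 0L) analysis_error("empty calibration pool")
  if (n < 20L) {
    warn(sprintf("calibration pool has only %d values; the percentile estimate is unstable", n))
  }
  stopifnot_scalar_number(target_specificity, "target_specificity", min = 0, max = 100)
  s <- sort(values)
  k <- ceiling(target_specificity / 100 * n)
  k <- min(max(k, 1L), n)
  value <- if (direction == "greater") s[k] else s[n - k + 1L]
  cutoff_spec(variable, dimension, direction, value, source = "calibrated")
}

#' Contingency counts of normal/abnormal results by diagnostic status
#'
#' @param nobos_normal,nobos_abnormal,bos_normal,bos_abnormal,bos0p_normal,bos0p_abnormal
#'   Non-negative counts of normal and abnormal test results among visits at
#'   which the patient's current status was NoBOS, BOS or BOS 0-p.
#' @return An object of class `contingency_counts` (a 3 x 2 integer matrix).
#' @export
contingency_counts <- function(nobos_normal, nobos_abnormal,
                               bos_normal, bos_abnormal,
                               bos0p_normal, bos0p_abnormal) {
  m <- matrix(
    c(nobos_normal, nobos_abnormal, bos_normal, bos_abnormal,
      bos0p_normal, bos0p_abnormal),
    nrow = 3, ncol = 2, byrow = TRUE,
    dimnames = list(c("NoBOS", "BOS", "BOS0p"), c("normal", "abnormal"))
  )
  if (any(m < 0) || anyNA(m)) config_error("counts must be non-negative")
  structure(m, class = c("contingency_counts", "matrix", "array"))
}

#' Tabulate normal/abnormal test results by current diagnostic status
#'
#' Pools every measurement of the cut-off's variable and dimension inside the
#' analysis window, classifies it by the cut-off, and bins it by the patient's
#' current diagnostic status at that visit (NoBOS pools the pre-onset visits
#' of future BOS patients too). Patients ending follow-up in BOS 0-p with an
#' unresolved outcome are excluded.
#'
#' @param normalized Output of [normalize_cohort()].
#' @param staging Output of [stage_cohort()] on the same cohort.
#' @param cutoff A [cutoff_spec()].
#' @param window Months interval of pooled results (default 6-36).
#' @param exclude_patients Patient ids to drop; defaults to the terminal
#'   BOS 0-p patients in `staging$outcomes`.
#' @return A [contingency_counts()] matrix.
#' @export
tabulate_counts <- function(normalized, staging, cutoff, window = c(6, 36),
                            exclude_patients = NULL) {
  if (is.null(exclude_patients)) {
    exclude_patients <- staging$outcomes$patient_id[staging$outcomes$terminal_bos0p]
  }
  col <- if (cutoff$dimension == "pct_basal") "pct_baseline" else "pct_predicted"
  meas <- dplyr::filter(
    normalized,
    .data$variable == cutoff$variable,
    .data$months_post_tx >= window[1], .data$months_post_tx <= window[2],
    !(.data$patient_id %in% exclude_patients)
  )
  if (col == "pct_baseline") {
    meas <- dplyr::filter(meas, !.data$baseline_provisional)
  }
  meas <- dplyr::inner_join(
    meas,
    dplyr::select(staging$staged, "patient_id", "months_post_tx", "status"),
    by = c("patient_id", "months_post_tx")
  )
  meas <- dplyr::filter(meas, !is.na(.data[[col]]))
  abn <- is_abnormal(meas[[col]], cutoff)
  count_cell <- function(status, abnormal) {
    sum(meas$status == status & abn == abnormal)
  }
  contingency_counts(
    count_cell("NoBOS", FALSE), count_cell("NoBOS", TRUE),
    count_cell("BOS", FALSE), count_cell("BOS", TRUE),
    count_cell("BOS0p", FALSE), count_cell("BOS0p", TRUE)
  )
}

#' Operating characteristics of a cut-off from contingency counts
#'
#' Per-measurement characteristics against the concurrent diagnostic status:
#' specificity on NoBOS visits, sensitivity for BOS and for BOS 0-p visits,
#' positive predictive values for BOS (BOS-abnormal over NoBOS- plus
#' BOS-abnormal) and for BOS plus BOS 0-p (over all abnormal), and the
#' corresponding negative predictive values. Reported percentages are rounded
#' half-up to integers; raw values are retained.
#'
#' @param counts A [contingency_counts()] matrix.
#' @return An object of class `operating_characteristics`: a list with
#'   `rounded` and `raw` named numeric vectors (entries NA when the
#'   denominator is zero).
#' @export
#' @examples
#' oc <- operating_characteristics(
#'   contingency_counts(264, 28, 0, 37, 0, 7)
#' )
#' oc$rounded
operating_characteristics <- function(counts) {
  if (!inherits(counts, "contingency_counts")) {
    config_error("`counts` must be a contingency_counts object")
  }
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  no_n <- counts["NoBOS", "normal"]; no_a <- counts["NoBOS", "abnormal"]
  b_n <- counts["BOS", "normal"]; b_a <- counts["BOS", "abnormal"]
  p_n <- counts["BOS0p", "normal"]; p_a <- counts["BOS0p", "abnormal"]
  raw <- c(
    specificity = ratio(no_n, no_n + no_a),
    sensitivity_bos = ratio(b_a, b_n + b_a),
    sensitivity_bos0p = ratio(p_a, p_n + p_a),
    ppv_bos = ratio(b_a, no_a + b_a),
    ppv_bos_plus_0p = ratio(b_a + p_a, no_a + b_a + p_a),
    npv_bos = ratio(no_n, no_n + b_n),
    npv_bos_plus_0p = ratio(no_n, no_n + b_n + p_n)
  )
  structure(
    list(raw = raw, rounded = round_half_up(raw), counts = counts),
    class = "operating_characteristics"
  )
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("<operating_characteristics>\n")
  print(x$rounded)
  invisible(x)
}

#' Patient-level performance of BOS 0-p as a predictor of BOS
#'
#' Patient-level two-by-two statistics of the potential-BOS stage: sensitivity
#' (BOS patients whose diagnosis was preceded by confirmed BOS 0-p),
#' specificity (never-BOS patients never staged BOS 0-p), and positive
#' predictive value (BOS 0-p patients who progressed to BOS over all
#' ever-BOS 0-p patients, terminal unresolved patients counted as
#' non-progressing). `counterfactual_progressors` reassigns that many terminal
#' patients as progressors in an alternative PPV.
#'
#' @param outcomes `outcomes` tibble from [stage_cohort()] (columns
#'   `bos_onset`, `ever_bos0p`, `bos0p_before_onset`, `terminal_bos0p`).
#' @param counterfactual_progressors Number of terminal BOS 0-p patients
#'   assumed, counterfactually, to progress (default 1).
#' @return List with `sensitivity`, `specificity`, `ppv`, `ppv_counterfactual`
#'   (rounded half-up percents), their `raw` values and the underlying
#'   `counts`.
#' @export
bos0p_predictor_stats <- function(outcomes, counterfactual_progressors = 1) {
  is_bos <- !is.na(outcomes$bos_onset)
  n_bos <- sum(is_bos)
  n_preceded <- sum(is_bos & outcomes$bos0p_before_onset)
  n_never <- sum(!is_bos)
  n_never_no0p <- sum(!is_bos & !outcomes$ever_bos0p)
  # ever-BOS 0-p patients: pre-onset 0-p among BOS patients, any confirmed or
  # terminal 0-p among the rest
  n_0p <- sum(ifelse(is_bos, outcomes$bos0p_before_onset, outcomes$ever_bos0p))
  n_progressed <- n_preceded
  n_terminal <- sum(outcomes$terminal_bos0p)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  k <- min(counterfactual_progressors, n_terminal)
  raw <- c(
    sensitivity = ratio(n_preceded, n_bos),
    specificity = ratio(n_never_no0p, n_never),
    ppv = ratio(n_progressed, n_0p),
    ppv_counterfactual = ratio(n_progressed + k, n_0p)
  )
  list(
    sensitivity = round_half_up(raw[["sensitivity"]]),
    specificity = round_half_up(raw[["specificity"]]),
    ppv = round_half_up(raw[["ppv"]]),
    ppv_counterfactual = round_half_up(raw[["ppv_counterfactual"]]),
    raw = raw,
    counts = c(n_bos = n_bos, n_preceded = n_preceded, n_never_bos = n_never,
               n_never_bos_never_0p = n_never_no0p, n_ever_0p = n_0p,
               n_progressed = n_progressed, n_terminal_0p = n_terminal)
  )
}
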