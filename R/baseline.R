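#' Post-transplant baseline of a lung-function variable
#'
#' The baseline is the mean of the two highest measurements taken at least
#' `min_separation_weeks` apart, considering only visits at or after
#' `earliest_months` post-transplant. While only one eligible measurement
#' exists the baseline equals that value and is flagged *provisional*;
#' provisional percent-of-baseline values are excluded from BOS staging.
#'
#' Because the eligible set only grows, the "latest baseline" recomputed at
#' each successive visit is non-decreasing.
#'
#' @param months Visit times in months post-transplant (chronological order).
#' @param values Measured values at those visits (same length; NAs allowed and
#'   skipped).
#' @param min_separation_weeks Minimum separation between the two contributing
#'   measurements, in weeks (default 3).
#' @param earliest_months Earliest visit eligible to contribute (default 4.5
#'   months post-transplant).
#' @return A list with `baseline` (NA if no eligible measurement),
#'   `provisional` (logical), and `contributors` (tibble of the contributing
#'   visit times and values).
#' @export
#' @examples
#' compute_baseline(c(4.5, 6, 9), c(2.8, 3.0, 3.2))$baseline # (3.0 + 3.2)/2
compute_baseline <- function(months, values,
                             min_separation_weeks = 3,
                             earliest_months = 4.5) {
  if (length(months) != length(values)) {
    config_error("`months` and `values` must have the same length")
  }
  keep <- !is.na(values) & months >= earliest_months
  m <- months[keep]
  v <- values[keep]
  n <- length(v)
  sep_months <- min_separation_weeks * 7 / 30.4375
  if (n == 0L) {
    return(list(baseline = NA_real_, provisional = TRUE,
                contributors = tibble::tibble(months = numeric(), value = numeric())))
  }
  if (n == 1L) {
    return(list(baseline = v, provisional = TRUE,
                contributors = tibble::tibble(months = m, value = v)))
  }
  # Best qualifying pair = the pair of values, >= sep_months apart, with the
  # largest mean. n is small (visit schedules have ~10 entries), so scan all
  # pairs.
  best <- -Inf
  best_pair <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(m[j] - m[i]) + 1e-9 >= sep_months) {
        mu <- (v[i] + v[j]) / 2
        if (mu > best) {
          best <- mu
          best_pair <- c(i, j)
        }
      }
    }
  }
  if (is.null(best_pair)) {
    # eligible visits exist but none far enough apart: fall back to the single
    # highest value, still provisional
    k <- which.max(v)
    return(list(baseline = v[k], provisional = TRUE,
                contributors = tibble::tibble(months = m[k], value = v[k])))
  }
  list(
    baseline = best,
    provisional = FALSE,
    contributors = tibble::tibble(months = m[best_pair], value = v[best_pair])
  )
}

#' Running ("latest") baselines along a timeline
#'
#' Recomputes the baseline at every visit from all eligible visits up to and
#' including that visit, mirroring how the baseline is tracked during
#' follow-up.
#'
#' @inheritParams compute_baseline
#' @return A tibble with one row per visit: `months`, `baseline`,
#'   `provisional`.
#' @export
running_baselines <- function(months, values,
                              min_separation_weeks = 3,
                              earliest_months = 4.5) {
  ord <- order(months)
  months <- months[ord]
  values <- values[ord]
  n <- length(months)
  baseline <- rep(NA_real_, n)
  provisional <- rep(TRUE, n)
  for (i in seq_len(n)) {
    st <- compute_baseline(months[seq_len(i)], values[seq_len(i)],
                           min_separation_weeks, earliest_months)
    baseline[i] <- st$baseline
    provisional[i] <- st$provisional
  }
  tibble::tibble(months = months, baseline = baseline, provisional = provisional)
}

#' Express a measurement in percent of the latest baseline
#'
#' @param value Measured value.
#' @param baseline Baseline value (> 0).
#' @return `100 * value / baseline`; NA when the baseline is absent.
#' @export
percent_of_baseline <- function(value, baseline) {
  if (any(!is.na(baseline) & baseline <= 0)) {
    analysis_error("baseline must be positive")
  }
  100 * value / baseline
}

#' Normalise a long-format visit table
#'
#' Adds, for every measurement, its percent of predicted normal
#' (`pct_predicted`) and its percent of the patient's latest baseline
#' (`pct_baseline`, with a `baseline_provisional` flag). The latest baseline
#' for each patient and variable is recomputed at every visit from all
#' eligible visits up to and including that visit (mean of the two highest
#' qualifying values; see [compute_baseline()]). Visits with a missing value
#' for a variable do not update that variable's baseline.
#'
#' @param visits Long-format visit tibble with columns `patient_id`, `sex`,
#'   `age_years`, `height_cm`, `months_post_tx`, `variable`, `value`.
#' @param refset Reference-equation table (see [default_reference_set()]).
#' @param min_separation_weeks,earliest_months Baseline eligibility rules
#'   passed to [compute_baseline()].
#' @return The input tibble with added columns `pct_predicted`, `baseline`,
#'   `baseline_provisional`, `pct_baseline`, sorted by patient, variable and
#'   time.
#' @export
normalize_cohort <- function(visits, refset = default_reference_set(),
                             min_separation_weeks = 3, earliest_months = 4.5) {
  needed <- c("patient_id", "sex", "age_years", "height_cm",
              "months_post_tx", "variable", "value")
  missing_cols <- setdiff(needed, names(visits))
  if (length(missing_cols) > 0) {
    validation_error(sprintf("visit table lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(visits) == 0L) {
    return(dplyr::mutate(visits,
                         pct_predicted = numeric(0), baseline = numeric(0),
                         baseline_provisional = logical(0), pct_baseline = numeric(0)))
  }
  visits <- dplyr::arrange(visits, .data$patient_id, .data$variable, .data$months_post_tx)
  visits$pct_predicted <- percent_predicted(
    visits$value, visits$variable, visits$sex,
    visits$age_years, visits$height_cm, refset
  )
  grouped <- dplyr::group_by(visits, .data$patient_id, .data$variable)
  out <- dplyr::mutate(grouped, {
    rb <- running_baselines(.data$months_post_tx, .data$value,
                            min_separation_weeks, earliest_months)
    tibble::tibble(baseline = rb$baseline, baseline_provisional = rb$provisional)
  })
  out <- dplyr::ungroup(out)
  out$pct_baseline <- percent_of_baseline(out$value, out$baseline)
  out
}
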