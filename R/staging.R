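#' BOS staging rules
#'
#' Stages are assigned from the FEV1 expressed in percent of the latest
#' post-transplant baseline: above 90% is NoBOS; a sustained 10-19% fall
#' (81-90%) is potential BOS (BOS 0-p); a sustained fall of 20% or more
#' (<= 80%) is BOS, subdivided into BOS 1 (66-80%), BOS 2 (51-65%) and BOS 3
#' (<= 50%). FEF25-75 is not used. A qualifying value is *confirmed* by the
#' next measurement at least `confirmation_separation_weeks` later lying at or
#' below the same band's upper bound.
#'
#' @param bos0p_band Percent-of-baseline band for BOS 0-p (default 81-90).
#' @param bos_threshold Upper percent-of-baseline bound for BOS (default 80).
#' @param substage_bounds Named list of (lower, upper) percent bounds for
#'   BOS1-BOS3.
#' @param confirmation_separation_weeks Minimum separation of the confirming
#'   measurement, weeks (default 3).
#' @param onset_dating `"first"` (default) dates BOS onset at the first
#'   measurement of the confirmed run; `"confirming"` dates it at the
#'   confirming measurement.
#' @return An object of class `stage_rules`.
#' @export
stage_rules <- function(bos0p_band = c(81, 90), bos_threshold = 80,
                        substage_bounds = list(BOS1 = c(66, 80),
                                               BOS2 = c(51, 65),
                                               BOS3 = c(0, 50)),
                        confirmation_separation_weeks = 3,
                        onset_dating = c("first", "confirming")) {
  onset_dating <- match.arg(onset_dating)
  if (bos_threshold != bos0p_band[1] - 1) {
    config_error("`bos_threshold` must equal the lower BOS 0-p bound minus 1")
  }
  structure(
    list(bos0p_band = bos0p_band, bos_threshold = bos_threshold,
         substage_bounds = substage_bounds,
         confirmation_separation_weeks = confirmation_separation_weeks,
         onset_dating = onset_dating),
    class = "stage_rules"
  )
}

bos_stage_levels <- function() c("NoBOS", "BOS0p", "BOS1", "BOS2", "BOS3")

#' Stage a single visit from FEV1 percent-of-baseline
#'
#' A monotone step function of percent-of-baseline: > 90 NoBOS, (80, 90]
#' BOS 0-p, (65, 80] BOS 1, (50, 65] BOS 2, <= 50 BOS 3 (default rules).
#'
#' @param fev1_pct_baseline FEV1 in percent of the latest baseline
#'   (vectorised).
#' @param rules A [stage_rules()].
#' @return Factor with levels NoBOS, BOS0p, BOS1, BOS2, BOS3.
#' @export
#' @examples
#' stage_visit(c(100, 85, 75, 60, 44))
stage_visit <- function(fev1_pct_baseline, rules = stage_rules()) {
  pct <- fev1_pct_baseline
  b <- rules$substage_bounds
  stage <- rep(NA_character_, length(pct))
  stage[pct > rules$bos0p_band[2]] <- "NoBOS"
  stage[pct <= rules$bos0p_band[2] & pct > rules$bos_threshold] <- "BOS0p"
  stage[pct <= b$BOS1[2] & pct > b$BOS2[2]] <- "BOS1"
  stage[pct <= b$BOS2[2] & pct > b$BOS3[2]] <- "BOS2"
  stage[pct <= b$BOS3[2]] <- "BOS3"
  factor(stage, levels = bos_stage_levels())
}

# upper bound of the band a stage belongs to, for confirmation: BOS 0-p
# confirms at <= 90, any BOS substage confirms at <= 80 (the substage may
# deepen between the pair; onset is defined by crossing 80)
band_upper <- function(stage, rules) {
  ifelse(stage == "BOS0p", rules$bos0p_band[2],
         ifelse(stage %in% c("BOS1", "BOS2", "BOS3"), rules$bos_threshold, Inf))
}

#' Confirm stages along one patient's timeline and locate BOS onset
#'
#' Walks a chronological timeline of staged visits. A visit at stage BOS 0-p
#' or deeper is confirmed when the next measurement at least
#' `confirmation_separation_weeks` later lies at or below the band's upper
#' bound. BOS onset is the time of the first measurement of the earliest
#' confirmed run at or below the BOS threshold. A qualifying value at the
#' final visit with no later measurement cannot be confirmed; when it lies in
#' the BOS 0-p band it yields the terminal flags instead of an onset.
#' Provisional-baseline visits are recorded as NoBOS and take no part in
#' confirmation.
#'
#' @param months Visit times in months post-transplant (chronological).
#' @param fev1_pct_baseline FEV1 percent-of-baseline at those visits.
#' @param provisional Logical: baseline still provisional at that visit
#'   (default all FALSE).
#' @param rules A [stage_rules()].
#' @return A list with `staged` (tibble: `months`, `fev1_pct_baseline`,
#'   `stage`, `confirmed`) and `outcome` (list: `bos_onset`, `ever_bos0p`,
#'   `bos0p_before_onset`, `terminal_bos0p`).
#' @export
#' @examples
#' confirm_stages(c(6, 9, 12, 18), c(100, 78, 75, 74))$outcome$bos_onset # 9
confirm_stages <- function(months, fev1_pct_baseline, provisional = NULL,
                           rules = stage_rules()) {
  n <- length(months)
  if (length(fev1_pct_baseline) != n) {
    config_error("`months` and `fev1_pct_baseline` must have the same length")
  }
  if (is.null(provisional)) provisional <- rep(FALSE, n)
  ord <- order(months)
  months <- months[ord]
  pct <- fev1_pct_baseline[ord]
  provisional <- provisional[ord]

  stage <- as.character(stage_visit(pct, rules))
  stage[provisional | is.na(pct)] <- "NoBOS"
  sep_months <- rules$confirmation_separation_weeks * 7 / 30.4375

  confirmed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (stage[i] == "NoBOS") next
    later <- which(months - months[i] + 1e-9 >= sep_months &
                     seq_len(n) > i & !provisional & !is.na(pct))
    if (length(later) == 0) next
    j <- later[1] # the next usable measurement far enough away
    confirmed[i] <- pct[j] <= band_upper(stage[i], rules)
  }

  bos_idx <- which(stage %in% c("BOS1", "BOS2", "BOS3") & confirmed)
  bos_onset <- NA_real_
  if (length(bos_idx) > 0) {
    i0 <- bos_idx[1]
    if (rules$onset_dating == "first") {
      bos_onset <- months[i0]
    } else {
      later <- which(months - months[i0] + 1e-9 >= sep_months & seq_len(n) > i0)
      bos_onset <- months[later[1]]
    }
  }

  terminal_bos0p <- is.na(bos_onset) && stage[n] == "BOS0p"
  ever_bos0p <- any(stage == "BOS0p" & confirmed) || terminal_bos0p
  bos0p_before_onset <- !is.na(bos_onset) &&
    any(stage == "BOS0p" & confirmed & months < bos_onset)

  list(
    staged = tibble::tibble(
      months = months, fev1_pct_baseline = pct,
      stage = factor(stage, levels = bos_stage_levels()), confirmed = confirmed
    ),
    outcome = list(
      bos_onset = bos_onset, ever_bos0p = ever_bos0p,
      bos0p_before_onset = bos0p_before_onset, terminal_bos0p = terminal_bos0p
    )
  )
}

#' Stage every patient of a normalised cohort
#'
#' Applies [confirm_stages()] to each patient's FEV1 percent-of-baseline
#' series and derives the per-visit *diagnostic status* used for pooled test
#' evaluation: `BOS` from the onset visit onward, `BOS0p` at confirmed
#' BOS 0-p visits before onset (and at a terminal BOS 0-p final visit),
#' `NoBOS` otherwise.
#'
#' @param normalized Output of [normalize_cohort()].
#' @param rules A [stage_rules()].
#' @return A list with `staged` (tibble: `patient_id`, `months_post_tx`,
#'   `fev1_pct_baseline`, `stage`, `confirmed`, `status`) and `outcomes`
#'   (tibble: `patient_id`, `bos_onset`, `ever_bos0p`, `bos0p_before_onset`,
#'   `terminal_bos0p`).
#' @export
stage_cohort <- function(normalized, rules = stage_rules()) {
  fev1 <- dplyr::filter(normalized, .data$variable == "FEV1")
  fev1 <- dplyr::arrange(fev1, .data$patient_id, .data$months_post_tx)
  split_f <- split(fev1, fev1$patient_id)
  staged_list <- vector("list", length(split_f))
  outcome_list <- vector("list", length(split_f))
  for (k in seq_along(split_f)) {
    df <- split_f[[k]]
    res <- confirm_stages(df$months_post_tx, df$pct_baseline,
                          df$baseline_provisional, rules)
    onset <- res$outcome$bos_onset
    st <- res$staged
    status <- ifelse(
      !is.na(onset) & st$months >= onset, "BOS",
      ifelse(as.character(st$stage) == "BOS0p" &
               (st$confirmed | seq_len(nrow(st)) == nrow(st)),
             "BOS0p", "NoBOS")
    )
    staged_list[[k]] <- tibble::tibble(
      patient_id = df$patient_id[1], months_post_tx = st$months,
      fev1_pct_baseline = st$fev1_pct_baseline, stage = st$stage,
      confirmed = st$confirmed, status = status
    )
    outcome_list[[k]] <- tibble::tibble(
      patient_id = df$patient_id[1],
      bos_onset = res$outcome$bos_onset,
      ever_bos0p = res$outcome$ever_bos0p,
      bos0p_before_onset = res$outcome$bos0p_before_onset,
      terminal_bos0p = res$outcome$terminal_bos0p
    )
  }
  list(staged = dplyr::bind_rows(staged_list),
       outcomes = dplyr::bind_rows(outcome_list))
}

#' Per-visit stage prevalence table
#'
#' Counts patients by assigned stage at each scheduled visit month (among
#' attended visits only, so column sums equal the number of patients still in
#' follow-up). Before onset a patient counts under their current status
#' (NoBOS or BOS 0-p); from onset onward under their current BOS substage.
#'
#' @param staged `staged` tibble from [stage_cohort()].
#' @param months_keep Visit months to report (default: 6 months onward).
#' @return A tibble with `stage` rows and one column per visit month.
#' @export
stage_prevalence <- function(staged, months_keep = NULL) {
  df <- staged
  if (!is.null(months_keep)) {
    df <- dplyr::filter(df, .data$months_post_tx %in% months_keep)
  }
  df$display <- ifelse(df$status == "BOS", as.character(df$stage),
                       ifelse(df$status == "BOS0p", "BOS0p", "NoBOS"))
  df$display <- factor(df$display, levels = bos_stage_levels())
  tab <- table(df$display, df$months_post_tx)
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "stage")
  out
}
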