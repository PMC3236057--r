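#' Configuration of a synthetic transplant cohort
#'
#' Defaults emulate a three-year bilateral lung / heart-lung transplant
#' follow-up programme: 61 recipients seen at 1, 2, 3, 4.5, 6, 9, 12, 18, 24
#' and 36 months post-transplant, about 15 of whom progress to BOS during
#' follow-up, 3 of whom end follow-up in the potential-BOS (BOS 0-p) band with
#' an unresolved outcome, and modest attrition from death or dropout.
#'
#' Disease trajectories are piecewise: a stable personal plateau for every
#' variable, then for BOS-destined patients a linear FEV1 decline that crosses
#' 80% of the plateau exactly at the assigned onset visit, while the N2-slope
#' rises multiplicatively (saturating toward several-fold its plateau)
#' starting `n2_lead_time_months` before the FEV1-defined onset. Measurement
#' noise is lognormal (relative), so all generated values stay positive.
#'
#' @param n_patients Number of recipients (default 61).
#' @param visit_schedule Months post-transplant of the scheduled visits
#'   (strictly increasing).
#' @param fraction_bos Proportion of patients progressing to BOS (default
#'   15/61).
#' @param fraction_terminal_bos0p Proportion ending follow-up in BOS 0-p with
#'   unresolved outcome (default 3/61).
#' @param bos_onset_range Months interval from which BOS onset visits are
#'   drawn; onsets land on scheduled visits that have at least one later visit
#'   so the diagnosis can be confirmed (default 9-24 months).
#' @param n2_lead_time_months Mean months by which the N2-slope rise precedes
#'   the FEV1-defined onset (default 6).
#' @param measurement_cv Relative measurement noise (coefficient of variation)
#'   per variable: a named vector, or a single number applied to every
#'   variable; 0 gives noiseless trajectories. Defaults reflect typical
#'   intra-subject repeatability: 3% for spirometry, 4-6% for plethysmographic
#'   volumes, 7% for CO-uptake and 8% for the N2-slope.
#' @param dropout_hazard Per-visit probability of ending follow-up after the
#'   first visit, for any patient (default 0.012, about 10% attrition of
#'   stable patients by 36 months).
#' @param bos_death_hazard Additional per-visit probability that a BOS patient
#'   dies, applied from two visits after onset (default 0.12); most deaths in
#'   such cohorts occur in established BOS.
#' @param fev1_ramp_range Months interval from which each BOS patient's
#'   pre-onset FEV1 ramp duration is drawn (default 4-8 months); the ramp
#'   never reaches back past the second baseline-eligible visit, so the
#'   baseline itself stays clean.
#' @param missing_prob Named per-variable probability that a scheduled
#'   measurement is missing; emulates the lower number of plethysmography,
#'   CO-uptake and washout occasions relative to spirometry.
#' @param seed Integer seed; identical seeds and configs give identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 61,
                          visit_schedule = c(1, 2, 3, 4.5, 6, 9, 12, 18, 24, 36),
                          fraction_bos = 15 / 61,
                          fraction_terminal_bos0p = 3 / 61,
                          bos_onset_range = c(9, 24),
                          n2_lead_time_months = 6,
                          measurement_cv = c(FEV1 = 0.03, FVC = 0.03,
                                             TLC = 0.04, FRC = 0.05, RV = 0.06,
                                             CO_uptake = 0.07, N2_slope = 0.08),
                          dropout_hazard = 0.012,
                          bos_death_hazard = 0.12,
                          fev1_ramp_range = c(4, 8),
                          missing_prob = c(FEV1 = 0, FVC = 0, TLC = 0.13,
                                           FRC = 0.13, RV = 0.13,
                                           CO_uptake = 0.1, N2_slope = 0.2),
                          seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", min = 0)
  if (length(visit_schedule) == 0L) config_error("`visit_schedule` must not be empty")
  if (any(diff(visit_schedule) <= 0)) {
    config_error("`visit_schedule` must be strictly increasing")
  }
  stopifnot_scalar_number(fraction_bos, "fraction_bos", min = 0, max = 1)
  stopifnot_scalar_number(fraction_terminal_bos0p, "fraction_terminal_bos0p",
                          min = 0, max = 1)
  if (fraction_bos + fraction_terminal_bos0p > 1) {
    config_error("`fraction_bos` + `fraction_terminal_bos0p` must be <= 1")
  }
  if (!is.numeric(measurement_cv) || any(is.na(measurement_cv)) ||
      any(measurement_cv < 0)) {
    config_error("`measurement_cv` must be non-negative")
  }
  if (length(measurement_cv) == 1L && is.null(names(measurement_cv))) {
    measurement_cv <- setNames(rep(measurement_cv, 7), lung_function_variables())
  }
  if (!all(lung_function_variables() %in% names(measurement_cv))) {
    config_error("`measurement_cv` must name every lung-function variable or be a single number")
  }
  stopifnot_scalar_number(dropout_hazard, "dropout_hazard", min = 0, max = 1)
  stopifnot_scalar_number(bos_death_hazard, "bos_death_hazard", min = 0, max = 1)
  if (length(bos_onset_range) != 2 || bos_onset_range[2] < bos_onset_range[1]) {
    config_error("`bos_onset_range` must be an increasing interval of months")
  }
  if (length(fev1_ramp_range) != 2 || any(fev1_ramp_range < 0) ||
      fev1_ramp_range[2] < fev1_ramp_range[1]) {
    config_error("`fev1_ramp_range` must be an increasing non-negative interval of months")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), visit_schedule = visit_schedule,
      fraction_bos = fraction_bos,
      fraction_terminal_bos0p = fraction_terminal_bos0p,
      bos_onset_range = bos_onset_range,
      n2_lead_time_months = n2_lead_time_months,
      measurement_cv = measurement_cv, dropout_hazard = dropout_hazard,
      bos_death_hazard = bos_death_hazard, fev1_ramp_range = fev1_ramp_range,
      missing_prob = missing_prob, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Stable personal plateaus in percent of predicted, lognormal around typical
# post-transplant medians (FEV1 ~85%, CO-uptake ~55%, N2-slope ~200% of
# predicted, i.e. abnormal even in stable recipients).
plateau_medians <- c(FEV1 = 0.85, FVC = 0.82, TLC = 0.89, FRC = 0.90,
                     RV = 1.00, CO_uptake = 0.55, N2_slope = 2.00)
plateau_sdlog <- c(FEV1 = 0.10, FVC = 0.10, TLC = 0.08, FRC = 0.10,
                   RV = 0.15, CO_uptake = 0.12, N2_slope = 0.25)

# FEV1 percent-of-plateau trajectory for one BOS-destined patient:
# piecewise-constant then linear — 1 up to ramp_start, a linear pre-onset
# decline reaching 0.76 exactly at onset (clearly past the 80% threshold so
# staging lands on the assigned visit under realistic noise; visits falling on
# the ramp may land in the BOS 0-p band, the potential-BOS prodrome), then a
# continued linear decline towards a personal floor.
fev1_multiplier <- function(months, onset, ramp_start, decline_rate, floor) {
  mult <- rep(1, length(months))
  if (ramp_start < onset) {
    ramp <- months > ramp_start & months < onset
    mult[ramp] <- 1 - 0.24 * (months[ramp] - ramp_start) / (onset - ramp_start)
  }
  post <- months >= onset
  mult[post] <- pmax(floor, 0.76 - decline_rate * (months[post] - onset))
  mult
}

# Saturating multiplicative N2-slope rise starting `rise_start`: toward
# `cap`-fold the plateau with time constant `tau` months.
n2_multiplier <- function(months, rise_start, cap, tau = 8) {
  mult <- rep(1, length(months))
  post <- months >= rise_start
  mult[post] <- 1 + (cap - 1) * (1 - exp(-(months[post] - rise_start) / tau))
  mult
}

#' Generate a seeded synthetic cohort
#'
#' Produces a long-format visit table (one row per patient, visit and
#' measured variable) together with a truth sidecar recording each patient's
#' assigned group, true BOS onset and N2-rise start, for parameter-recovery
#' tests.
#'
#' @param config A [cohort_config()].
#' @return An object of class `bos_cohort`: a list with `visits` (tibble:
#'   `patient_id`, `sex`, `age_years`, `height_cm`, `months_post_tx`,
#'   `variable`, `value`), `truth` (tibble: `patient_id`, `group`,
#'   `bos_onset_true`, `n2_rise_start`, `fev1_ramp_start`, `last_visit`) and
#'   the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 8, seed = 7))
#' dplyr::count(cohort$truth, group)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config_error("`config` must be a cohort_config object")
  }
  vars <- lung_function_variables()
  empty <- list(
    visits = tibble::tibble(
      patient_id = character(), sex = character(), age_years = numeric(),
      height_cm = numeric(), months_post_tx = numeric(),
      variable = character(), value = numeric()
    ),
    truth = tibble::tibble(
      patient_id = character(), group = character(),
      bos_onset_true = numeric(), n2_rise_start = numeric(),
      fev1_ramp_start = numeric(), last_visit = numeric()
    ),
    config = config
  )
  if (config$n_patients == 0L) {
    return(structure(empty, class = "bos_cohort"))
  }

  with_seed(config$seed, {
    n <- config$n_patients
    schedule <- config$visit_schedule
    refset <- default_reference_set()
    cv <- config$measurement_cv[vars]
    sdlog <- ifelse(cv > 0, sqrt(log(1 + cv^2)), 0)

    n_bos <- round(config$fraction_bos * n)
    n_term <- round(config$fraction_terminal_bos0p * n)
    group <- rep("stable", n)
    picks <- sample.int(n, n_bos + n_term)
    group[picks[seq_len(n_bos)]] <- "bos"
    if (n_term > 0) group[picks[n_bos + seq_len(n_term)]] <- "terminal_bos0p"

    # candidate onset visits: inside the range and not the last scheduled
    # visit (the diagnosis needs a later confirming measurement)
    onset_candidates <- schedule[
      schedule >= config$bos_onset_range[1] &
        schedule <= config$bos_onset_range[2] &
        schedule < schedule[length(schedule)]
    ]
    if (n_bos > 0 && length(onset_candidates) == 0L) {
      config_error("`bos_onset_range` contains no confirmable scheduled visit")
    }

    visits_list <- vector("list", n)
    truth_list <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- sprintf("P%03d", i)
      sex <- sample(c("F", "M"), 1, prob = c(0.54, 0.46))
      age <- runif(1, 16, 58)
      height <- if (sex == "M") {
        min(max(rnorm(1, 177, 7), 155), 198)
      } else {
        min(max(rnorm(1, 164, 7), 148), 185)
      }
      plateau <- predicted_value(vars, sex, age, height, refset) *
        plateau_medians[vars] * exp(rnorm(length(vars), 0, plateau_sdlog[vars]))
      names(plateau) <- vars

      onset <- NA_real_
      ramp_start <- NA_real_
      rise_start <- NA_real_
      if (group[i] == "bos") {
        onset <- if (length(onset_candidates) == 1L) onset_candidates else
          sample(onset_candidates, 1)
        # pre-onset FEV1 ramp, kept clear of the first two baseline-eligible
        # visits so the baseline itself is unaffected
        ramp_len <- runif(1, config$fev1_ramp_range[1], config$fev1_ramp_range[2])
        elig <- schedule[schedule >= 4.5]
        min_clean <- if (length(elig) >= 2) elig[2] + 0.001 else onset
        ramp_start <- max(onset - ramp_len, min_clean)
        rise_start <- onset - max(1.5, rnorm(1, config$n2_lead_time_months, 2))
      }

      # follow-up truncation by death/dropout: per-visit hazard after visit 1
      k_last <- length(schedule)
      if (config$dropout_hazard > 0 && length(schedule) > 1) {
        drops <- which(rbinom(length(schedule) - 1L, 1, config$dropout_hazard) == 1)
        if (length(drops) > 0) k_last <- drops[1]
      }
      if (group[i] == "bos") {
        onset_idx <- match(onset, schedule)
        # survive at least two visits past onset so a one-visit-late staged
        # onset can still be confirmed ...
        k_last <- max(k_last, onset_idx + 2L)
        # ... then face an extra per-visit death hazard in established BOS
        if (config$bos_death_hazard > 0 && k_last > onset_idx + 2L) {
          later <- (onset_idx + 3L):k_last
          dies <- which(rbinom(length(later), 1, config$bos_death_hazard) == 1)
          if (length(dies) > 0) k_last <- later[dies[1]] - 1L
        }
      }
      if (group[i] == "terminal_bos0p") {
        # attend at least up to the third eligible (>= 4.5 month) visit so two
        # clean baseline visits precede the terminal BOS 0-p value
        idx_elig <- which(schedule >= 4.5)
        if (length(idx_elig) >= 3) k_last <- max(k_last, idx_elig[3])
      }
      k_last <- min(k_last, length(schedule))
      attended <- schedule[seq_len(k_last)]
      last_visit <- attended[length(attended)]

      mult <- matrix(1, nrow = length(attended), ncol = length(vars),
                     dimnames = list(NULL, vars))
      if (group[i] == "bos") {
        decline_rate <- runif(1, 0.010, 0.025) # per month
        floor_frac <- runif(1, 0.35, 0.55)
        m_fev1 <- fev1_multiplier(attended, onset, ramp_start, decline_rate, floor_frac)
        mult[, "FEV1"] <- m_fev1
        mult[, "FVC"] <- (m_fev1 + 1) / 2        # restrictive loss about half as deep
        mult[, "RV"] <- 2 - m_fev1               # air trapping as obstruction deepens
        mult[, "N2_slope"] <- n2_multiplier(attended, rise_start, cap = runif(1, 4, 6))
      } else if (group[i] == "terminal_bos0p") {
        mult[length(attended), "FEV1"] <- 0.85
        mult[length(attended), "N2_slope"] <- 1.5
      }

      value <- sweep(mult, 2, plateau[vars], `*`)
      if (any(sdlog > 0)) {
        noise_sd <- rep(sdlog, each = nrow(value)) # column-major: one sd per variable column
        value <- value * exp(matrix(rnorm(length(value), 0, noise_sd), nrow = nrow(value)))
      }
      df <- tibble::tibble(
        patient_id = pid, sex = sex, age_years = age, height_cm = height,
        months_post_tx = rep(attended, times = length(vars)),
        variable = rep(vars, each = length(attended)),
        value = as.vector(value)
      )
      # per-variable missingness (never for FEV1/FVC by default)
      mp <- config$missing_prob[df$variable]
      mp[is.na(mp)] <- 0
      keep <- runif(nrow(df)) >= mp
      visits_list[[i]] <- df[keep, ]
      truth_list[[i]] <- tibble::tibble(
        patient_id = pid, group = group[i], bos_onset_true = onset,
        n2_rise_start = rise_start, fev1_ramp_start = ramp_start,
        last_visit = last_visit
      )
    }

    structure(
      list(
        visits = dplyr::bind_rows(visits_list),
        truth = dplyr::bind_rows(truth_list),
        config = config
      ),
      class = "bos_cohort"
    )
  })
}

#' @export
print.bos_cohort <- function(x, ...) {
  cat(sprintf(
    "<bos_cohort> %d patients (%d BOS, %d terminal BOS 0-p), %d measurements\n",
    nrow(x$truth), sum(x$truth$group == "bos"),
    sum(x$truth$group == "terminal_bos0p"), nrow(x$visits)
  ))
  invisible(x)
}
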