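test_that("percent of predicted is the ratio to the reference equation", {
  refset <- default_reference_set()
  pred <- predicted_value("FEV1", "M", 40, 178, refset)
  expect_equal(percent_predicted(pred, "FEV1", "M", 40, 178, refset), 100)
  expect_equal(percent_predicted(2 * pred, "FEV1", "M", 40, 178, refset), 200)
  # a severely obstructed FEV1 of 1.32 L against a 3.0 L prediction is 44%
  refset_3L <- data.frame(variable = "FEV1", sex = "M", intercept = 3,
                          age_coef = 0, height_coef = 0)
  expect_equal(percent_predicted(1.32, "FEV1", "M", 40, 178, refset_3L), 44)
  expect_error(percent_predicted(1, "XYZ", "M", 40, 178, refset),
               class = "bosn2_config_error")
})

test_that("baseline is the best qualifying pair mean and grows monotonically", {
  expect_equal(compute_baseline(c(4.5, 6), c(3.0, 3.0))$baseline, 3.0)
  expect_equal(compute_baseline(c(4.5, 6, 9), c(2.8, 3.0, 3.2))$baseline, 3.1)
  # a new lower value leaves the baseline unchanged
  expect_equal(compute_baseline(c(4.5, 6, 9, 12), c(2.8, 3.0, 3.2, 2.0))$baseline, 3.1)
  # visits before 4.5 months never contribute
  expect_equal(compute_baseline(c(1, 2, 4.5, 6), c(9, 9, 3.0, 3.2))$baseline, 3.1)
})

test_that("baseline equals a brute-force maximum over qualifying pairs", {
  sep <- 3 * 7 / 30.4375
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    months <- sort(runif(n, 0, 36))
    values <- runif(n, 2, 4)
    st <- compute_baseline(months, values)
    elig <- which(months >= 4.5)
    if (length(elig) >= 2) {
      pairs <- utils::combn(elig, 2)
      ok <- abs(months[pairs[2, ]] - months[pairs[1, ]]) + 1e-9 >= sep
      if (any(ok)) {
        oracle <- max((values[pairs[1, ok]] + values[pairs[2, ok]]) / 2)
        expect_false(st$provisional)
        expect_equal(st$baseline, oracle)
        # the larger contributor always sits at or above the pair mean
        expect_gte(max(st$contributors$value), st$baseline)
      }
    }
  }
})

test_that("single eligible visits give a provisional baseline", {
  st <- compute_baseline(c(1, 6), c(3.5, 3.0))
  expect_true(st$provisional)
  expect_equal(st$baseline, 3.0)
  # two eligible visits too close together also stay provisional
  st2 <- compute_baseline(c(4.5, 4.6), c(3.0, 3.2))
  expect_true(st2$provisional)
  expect_equal(st2$baseline, 3.2)
  expect_true(is.na(compute_baseline(numeric(), numeric())$baseline))
})

test_that("running baselines never decrease along a timeline", {
  set.seed(7)
  for (rep in 1:10) {
    months <- c(1, 2, 3, 4.5, 6, 9, 12, 18, 24, 36)
    values <- rlnorm(10, log(3), 0.1)
    rb <- running_baselines(months, values)
    # once confirmed (two qualifying contributors), the baseline is the max
    # pair mean over a growing set, hence non-decreasing; a provisional
    # single-value baseline may sit above the first confirmed pair mean
    b <- rb$baseline[!rb$provisional & !is.na(rb$baseline)]
    expect_true(all(diff(b) >= -1e-12))
  }
})

test_that("percent of baseline is the plain ratio with guarded degenerate input", {
  expect_equal(percent_of_baseline(3, 3), 100)
  expect_equal(percent_of_baseline(2.4, 3.0), 80)
  expect_equal(percent_of_baseline(2.7, 3.0), 90)
  expect_error(percent_of_baseline(1, 0), class = "bosn2_analysis_error")
})

test_that("normalize_cohort adds consistent percent columns for every measurement", {
  cohort <- generate_cohort(cohort_config(n_patients = 12, seed = 3))
  norm <- normalize_cohort(cohort$visits)
  expect_equal(nrow(norm), nrow(cohort$visits))
  expect_true(all(c("pct_predicted", "pct_baseline", "baseline_provisional")
                  %in% names(norm)))
  chk <- dplyr::summarise(
    dplyr::group_by(norm, patient_id, variable),
    nondecreasing = all(diff(baseline[!baseline_provisional & !is.na(baseline)])
                        >= -1e-12),
    .groups = "drop"
  )
  expect_true(all(chk$nondecreasing))
  expect_true(all(norm$pct_predicted > 0))
})
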