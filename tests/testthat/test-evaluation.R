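test_that("calibrated cut-offs classify exactly the target tail on a 1..100 pool", {
  up <- calibrate_cutoff(1:100, "greater", 95)
  expect_equal(sum(is_abnormal(1:100, up)), 5)
  lo <- calibrate_cutoff(1:100, "less", 95)
  expect_equal(sum(is_abnormal(1:100, lo)), 5)
  const <- suppressWarnings(calibrate_cutoff(rep(7, 20), "greater", 95))
  expect_gte(const$value, 7)
  expect_equal(sum(is_abnormal(rep(7, 20), const)), 0)
  expect_error(calibrate_cutoff(numeric(), "greater"),
               class = "bosn2_analysis_error")
  expect_warning(calibrate_cutoff(1:10, "greater"), "unstable")
})

test_that("calibration is self-consistent on its own pool", {
  set.seed(99)
  for (n in c(50, 500, 5000)) {
    for (dir in c("greater", "less")) {
      pool <- rlnorm(n, log(200), 0.4)
      co <- calibrate_cutoff(pool, dir, 95)
      spec <- 100 * sum(!is_abnormal(pool, co)) / n
      expect_gte(spec, 95)
      expect_lte(spec, 95 + 100 / n)
    }
  }
})

test_that("operating characteristics reproduce published cells from published counts", {
  # FEV1 < 90% basal row
  oc <- operating_characteristics(contingency_counts(264, 28, 0, 37, 0, 7))
  expect_equal(unname(oc$rounded),
               c(90, 100, 100, 57, 61, 100, 100))
  # N2-slope > 478% predicted row
  oc <- operating_characteristics(contingency_counts(234, 18, 1, 24, 0, 7))
  expect_equal(unname(oc$rounded["specificity"]), 93)
  expect_equal(unname(oc$rounded["sensitivity_bos"]), 96)
  expect_equal(unname(oc$rounded["sensitivity_bos0p"]), 100)
  expect_equal(unname(oc$rounded["ppv_bos"]), 57)
  expect_equal(unname(oc$rounded["ppv_bos_plus_0p"]), 63)
})

test_that("degenerate contingency tables give perfect or undefined metrics", {
  oc <- operating_characteristics(contingency_counts(10, 0, 0, 10, 0, 0))
  expect_equal(unname(oc$rounded["specificity"]), 100)
  expect_equal(unname(oc$rounded["sensitivity_bos"]), 100)
  expect_equal(unname(oc$rounded["ppv_bos"]), 100)
  expect_true(is.na(oc$rounded["sensitivity_bos0p"])) # no BOS 0-p visits
  expect_error(contingency_counts(-1, 0, 0, 0, 0, 0),
               class = "bosn2_config_error")
})

test_that("tabulated counts equal a direct per-measurement reclassification", {
  b <- default_pipeline()
  co <- b$cutoffs[["N2_slope_pct_pred"]]
  counts <- b$counts[["N2_slope_pct_pred"]]
  # independent recount: iterate rows, classify, bin by joined status
  excl <- b$staging$outcomes$patient_id[b$staging$outcomes$terminal_bos0p]
  df <- merge(
    b$normalized[b$normalized$variable == "N2_slope", ],
    b$staging$staged[, c("patient_id", "months_post_tx", "status")],
    by = c("patient_id", "months_post_tx")
  )
  df <- df[df$months_post_tx >= 6 & df$months_post_tx <= 36 &
             !(df$patient_id %in% excl) & !is.na(df$pct_predicted), ]
  abn <- df$pct_predicted > co$value
  for (stt in c("NoBOS", "BOS", "BOS0p")) {
    expect_equal(counts[stt, "normal"], sum(df$status == stt & !abn))
    expect_equal(counts[stt, "abnormal"], sum(df$status == stt & abn))
  }
})

test_that("evaluation and calibration pools can differ, shifting specificity", {
  # calibrate on stable patients only, evaluate on everyone's NoBOS visits:
  # the evaluation pool is a superset, so its specificity may differ from 95
  b <- default_pipeline()
  co <- b$cutoffs[["N2_slope_pct_pred"]]
  pool <- bosn2:::stable_pool(b$normalized, b$staging, "N2_slope", "pct_pred",
                              c(6, 36))
  self_spec <- 100 * sum(!is_abnormal(pool, co)) / length(pool)
  expect_gte(self_spec, 95)
  eval_spec <- b$characteristics[["N2_slope_pct_pred"]]$raw["specificity"]
  expect_false(isTRUE(all.equal(unname(eval_spec), self_spec)))
})

test_that("patient-level BOS 0-p statistics match the published patient counts", {
  outcomes <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:61),
    bos_onset = c(rep(12, 15), rep(NA, 46)),
    bos0p_before_onset = c(rep(TRUE, 4), rep(FALSE, 57)),
    ever_bos0p = c(rep(TRUE, 4), rep(FALSE, 11), rep(TRUE, 3), rep(FALSE, 43)),
    terminal_bos0p = c(rep(FALSE, 15), rep(TRUE, 3), rep(FALSE, 43))
  )
  st <- bos0p_predictor_stats(outcomes)
  expect_equal(st$sensitivity, 27) # 4 of 15
  expect_equal(st$specificity, 93) # 43 of 46
  expect_equal(st$ppv, 57)         # 4 of 7
  expect_equal(st$ppv_counterfactual, 71) # 5 of 7
})

test_that("reporting rounds halves upward", {
  expect_equal(round_half_up(c(54.5, 99.6, 26.67, 92.857)), c(55, 100, 27, 93))
  expect_equal(round_half_up(-54.5), -55)
})
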