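test_that("predictive value is the rounded share of abnormal results preceding BOS", {
  expect_equal(prediction_counts(299, 28, 11)$predictive_value, 39)
  expect_equal(prediction_counts(259, 22, 12)$predictive_value, 55) # 54.5 rounds up
  expect_equal(prediction_counts(259, 12, 9)$predictive_value, 75)
  expect_equal(prediction_counts(10, 5, 5)$predictive_value, 100)
  expect_true(is.na(prediction_counts(10, 0, 0)$predictive_value))
  expect_error(prediction_counts(10, 5, 6), class = "bosn2_config_error")
  expect_error(prediction_counts(10, 11, 5), class = "bosn2_config_error")
})

test_that("predictive-ability pooling matches a brute-force recount", {
  b <- default_pipeline()
  pc <- b$prediction$n2
  co <- b$cutoffs[["N2_slope_pct_pred"]]
  excl <- b$staging$outcomes$patient_id[b$staging$outcomes$terminal_bos0p]
  onset <- setNames(b$staging$outcomes$bos_onset, b$staging$outcomes$patient_id)
  df <- b$normalized[b$normalized$variable == "N2_slope" &
                       b$normalized$months_post_tx >= 6 &
                       b$normalized$months_post_tx <= 24 &
                       !(b$normalized$patient_id %in% excl) &
                       !is.na(b$normalized$pct_predicted), ]
  ons <- unname(onset[df$patient_id])
  pre <- is.na(ons) | df$months_post_tx < ons
  df <- df[pre, ]; ons <- ons[pre]
  abn <- df$pct_predicted > co$value
  expect_equal(pc$total_results, nrow(df))
  expect_equal(pc$total_abnormal, sum(abn))
  expect_equal(pc$abnormal_preceding_bos,
               sum(abn & !is.na(ons) & df$months_post_tx < ons))
})

test_that("no pooled occasion falls at or after the diagnosis", {
  b <- default_pipeline()
  occ <- bosn2:::prediction_occasions(
    b$normalized, b$staging,
    prediction_criterion(b$cutoffs[["FEV1_pct_basal"]])
  )
  onset <- setNames(b$staging$outcomes$bos_onset, b$staging$outcomes$patient_id)
  ons <- unname(onset[occ$patient_id])
  expect_true(all(is.na(ons) | occ$months_post_tx < ons))
  # and the truth sidecar agrees: no occasion at or beyond the true onset
  truth_onset <- setNames(b$cohort$truth$bos_onset_true, b$cohort$truth$patient_id)
  tons <- unname(truth_onset[occ$patient_id])
  expect_true(all(is.na(tons) | occ$months_post_tx <= tons))
})

test_that("combined-criterion abnormal occasions are a subset of each component's", {
  b <- default_pipeline()
  fe <- b$cutoffs[["FEV1_pct_basal"]]
  n2 <- b$cutoffs[["N2_slope_pct_pred"]]
  get_abn <- function(cr) {
    occ <- bosn2:::prediction_occasions(b$normalized, b$staging, cr)
    occ[occ$abnormal, c("patient_id", "months_post_tx")]
  }
  both <- get_abn(prediction_criterion(fe, n2))
  single_f <- get_abn(prediction_criterion(fe))
  single_n <- get_abn(prediction_criterion(n2))
  key <- function(d) paste(d$patient_id, d$months_post_tx)
  expect_true(all(key(both) %in% key(single_f)))
  expect_true(all(key(both) %in% key(single_n)))
  expect_lte(nrow(both), min(nrow(single_f), nrow(single_n)))
})

test_that("the abnormal-occasion histogram totals match the prediction counts", {
  b <- default_pipeline()
  cr <- prediction_criterion(b$cutoffs[["FEV1_pct_basal"]],
                             b$cutoffs[["N2_slope_pct_pred"]])
  hist <- combined_abnormal_timeline(b$normalized, b$staging, cr)
  pc <- b$prediction$combined
  expect_equal(sum(hist$n_abnormal), pc$total_abnormal)
  expect_equal(sum(hist$n_preceding_bos), pc$abnormal_preceding_bos)
  # an empty window gives an empty histogram
  empty <- combined_abnormal_timeline(b$normalized, b$staging, cr,
                                      window = c(100, 200))
  expect_equal(nrow(empty), 0)
  # a single-component histogram recounts that component's prediction counts
  h1 <- combined_abnormal_timeline(
    b$normalized, b$staging, prediction_criterion(b$cutoffs[["N2_slope_pct_pred"]])
  )
  expect_equal(sum(h1$n_abnormal), b$prediction$n2$total_abnormal)
})

test_that("a longer N2 lead time never reduces abnormal results preceding BOS", {
  run_with_lead <- function(lead) {
    cfg <- cohort_config(seed = 31, n2_lead_time_months = lead)
    b <- run_pipeline(config = cfg)
    b$prediction$n2$abnormal_preceding_bos
  }
  expect_gte(run_with_lead(10), run_with_lead(5))
})
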