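test_that("stage assignment is a monotone step function of percent-of-baseline", {
  expect_equal(
    as.character(stage_visit(c(100, 91, 90, 85, 81, 80, 66, 65, 51, 50, 44))),
    c("NoBOS", "NoBOS", "BOS0p", "BOS0p", "BOS0p", "BOS1", "BOS1",
      "BOS2", "BOS2", "BOS3", "BOS3")
  )
  pct <- seq(30, 110, by = 0.5)
  codes <- as.integer(stage_visit(pct))
  expect_true(all(diff(codes) <= 0)) # deeper stages at lower percentages
})

test_that("confirmation logic locates onset and terminal potential BOS", {
  # persistently normal timeline
  r <- confirm_stages(c(6, 9, 12), c(100, 100, 100))
  expect_true(is.na(r$outcome$bos_onset))
  expect_false(r$outcome$ever_bos0p)

  # sustained decline: onset at the first measurement of the confirmed run
  r <- confirm_stages(c(6, 9, 12, 18), c(100, 78, 75, 74))
  expect_equal(r$outcome$bos_onset, 9)
  expect_equal(as.character(r$staged$stage), c("NoBOS", "BOS1", "BOS1", "BOS1"))
  expect_true(all(r$staged$confirmed[2:3]))

  # optional dating at the confirming measurement
  r2 <- confirm_stages(c(6, 9, 12, 18), c(100, 78, 75, 74),
                       rules = stage_rules(onset_dating = "confirming"))
  expect_equal(r2$outcome$bos_onset, 12)

  # an unconfirmed BOS 0-p value at the final visit: terminal flags, no onset
  r <- confirm_stages(c(6, 9, 12), c(100, 100, 85))
  expect_true(is.na(r$outcome$bos_onset))
  expect_true(r$outcome$ever_bos0p)
  expect_true(r$outcome$terminal_bos0p)

  # a transient dip that recovers is never confirmed
  r <- confirm_stages(c(6, 9, 12, 18), c(100, 85, 100, 100))
  expect_false(r$outcome$ever_bos0p)
  expect_false(any(r$staged$confirmed))
})

test_that("BOS 0-p preceding BOS is recognised from a prodrome", {
  r <- confirm_stages(c(6, 9, 12, 18), c(100, 86, 74, 70))
  expect_equal(r$outcome$bos_onset, 12)
  expect_true(r$outcome$bos0p_before_onset)
  expect_false(r$outcome$terminal_bos0p)
})

test_that("provisional-baseline visits are recorded NoBOS and never confirm", {
  r <- confirm_stages(c(4.5, 6, 9), c(70, 70, 70),
                      provisional = c(TRUE, FALSE, FALSE))
  expect_equal(as.character(r$staged$stage)[1], "NoBOS")
  expect_equal(r$outcome$bos_onset, 6)
})

test_that("onsets are recovered exactly on a noiseless cohort", {
  cohort <- generate_cohort(noiseless_config())
  norm <- normalize_cohort(cohort$visits)
  st <- stage_cohort(norm)
  m <- dplyr::inner_join(cohort$truth, st$outcomes, by = "patient_id")
  bos <- m[m$group == "bos", ]
  expect_true(all(!is.na(bos$bos_onset)))
  expect_equal(bos$bos_onset, bos$bos_onset_true)
  stable <- m[m$group == "stable", ]
  expect_true(all(is.na(stable$bos_onset)))
  expect_false(any(stable$ever_bos0p))
  term <- m[m$group == "terminal_bos0p", ]
  expect_true(all(term$terminal_bos0p))
})

test_that("a no-signal cohort stages every patient NoBOS at every visit", {
  cfg <- cohort_config(n_patients = 10, fraction_bos = 0,
                       fraction_terminal_bos0p = 0, measurement_cv = 0,
                       seed = 2)
  st <- stage_cohort(normalize_cohort(generate_cohort(cfg)$visits))
  expect_true(all(st$staged$stage == "NoBOS"))
  expect_true(all(is.na(st$outcomes$bos_onset)))
})

test_that("stage prevalence rows sum to patients still in follow-up", {
  b <- default_pipeline()
  tab <- b$stage_table
  alive <- colSums(as.matrix(tab[, -1]))
  expect_true(all(diff(alive) <= 0))
  attended <- table(b$staging$staged$months_post_tx)
  expect_equal(unname(alive),
               unname(as.integer(attended[colnames(tab)[-1]])))
})
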