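test_that("the phase III slope is recovered exactly on noiseless tracings", {
  for (s3 in c(0, 0.5, 1.5, 3)) {
    for (cv in c(0, 0.6, 1.2)) {
      p <- tracing_params(phase3_slope = s3, closing_volume = cv,
                          phase4_slope = if (cv > 0) s3 + 5 else s3,
                          noise_sd = 0)
      res <- compute_n2_slope(generate_washout_tracing(p))
      expect_lt(abs(res$slope - s3), 1e-9)
      if (cv > 0) {
        expect_lt(abs(res$closing_point_volume - (p$vital_capacity - cv)),
                  p$sample_spacing + 1e-12)
      } else {
        expect_equal(res$closing_point_volume, p$vital_capacity)
      }
    }
  }
})

test_that("detected closing point matches a brute-force two-segment oracle", {
  p <- tracing_params(phase3_slope = 1.2, closing_volume = 0.8,
                      phase4_slope = 5, noise_sd = 0)
  tr <- generate_washout_tracing(p)
  cfg <- slope_config()
  idx <- which(tr$expired_volume >= cfg$proximal_offset)
  v <- tr$expired_volume[idx]
  y <- tr$n2[idx]
  m <- length(v)
  # independent oracle: refit both segments with lm() at every split
  rss <- sapply(2:(m - 2), function(k) {
    f1 <- lm(y[1:k] ~ v[1:k])
    f2 <- lm(y[(k + 1):m] ~ v[(k + 1):m])
    sum(resid(f1)^2) + sum(resid(f2)^2)
  })
  oracle_cp <- v[(2:(m - 2))[which.min(rss)]]
  expect_lt(abs(detect_closing_point(tr, cfg) - oracle_cp),
            p$sample_spacing + 1e-12)
})

test_that("tracings without a phase IV report the closing point at end of expiration", {
  p <- tracing_params(phase3_slope = 1.5, phase4_slope = 1.5,
                      closing_volume = 0.9, noise_sd = 0)
  expect_equal(detect_closing_point(generate_washout_tracing(p)),
               p$vital_capacity)
})

test_that("tracings truncated near the proximal offset raise an analysis error", {
  tr <- washout_tracing(seq(0, 1.0, by = 0.02), rep(20, 51))
  expect_error(detect_closing_point(tr), class = "bosn2_analysis_error")
  expect_error(compute_n2_slope(tr), class = "bosn2_analysis_error")
})

test_that("slope is invariant to concentration shifts and scales inversely with volume", {
  p <- tracing_params(phase3_slope = 1.8, closing_volume = 0.9,
                      phase4_slope = 6, noise_sd = 0.15, seed = 21)
  tr <- generate_washout_tracing(p)
  base <- compute_n2_slope(tr)

  shifted <- washout_tracing(tr$expired_volume, tr$n2 + 5,
                             tr$vital_capacity, tr$tlc)
  expect_equal(compute_n2_slope(shifted)$slope, base$slope, tolerance = 1e-12)

  k <- 2
  scaled <- washout_tracing(tr$expired_volume * k, tr$n2,
                            tr$vital_capacity * k,
                            if (is.null(tr$tlc)) NULL else tr$tlc * k)
  cfg_k <- slope_config(proximal_offset = 0.825 * k, min_window = 0.3 * k)
  expect_equal(compute_n2_slope(scaled, cfg_k)$slope, base$slope / k,
               tolerance = 1e-12)
})

test_that("noisy slope estimates are unbiased across seeded replicates", {
  est <- vapply(1:50, function(s) {
    tr <- generate_washout_tracing(
      tracing_params(phase3_slope = 1.5, noise_sd = 0.2, seed = s)
    )
    compute_n2_slope(tr)$slope
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.15)
})

test_that("averaging recordings takes the arithmetic mean of slopes", {
  mk <- function(s) structure(
    list(slope = s, closing_point_volume = 3.6,
         window = c(start = 0.825, end = 3.6), n_samples_used = 100),
    class = "n2_slope_result"
  )
  expect_equal(average_recordings(list(mk(2)))$slope, 2)
  expect_equal(average_recordings(list(mk(1), mk(3)))$slope, 2)
  expect_equal(average_recordings(list(mk(1), mk(2), mk(3)))$slope, 2)
  expect_equal(average_recordings(list(mk(1), mk(3)))$closing_point_volume, 3.6)
  expect_error(average_recordings(list()), class = "bosn2_analysis_error")
})
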