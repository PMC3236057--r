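# Shared fixtures: all built in code at test time.

# Published operating characteristics (42 cells) for the six packaged
# cut-offs, in the row order of reference_test_counts(): specificity,
# sensitivity (BOS, BOS 0-p), PPV (BOS, BOS + BOS 0-p), NPV (BOS,
# BOS + BOS 0-p), all integer percent.
expected_reference_oc <- function() {
  m <- rbind(
    c(90, 100, 100, 57, 61, 100, 100), # FEV1  % basal  < 90
    c(96, 77, 17, 71, 72, 97, 96),     # FVC   % basal  < 90
    c(95, 52, 43, 52, 57, 95, 94),     # N2    % basal  > 299
    c(95, 67, 0, 63, 63, 96, 94),      # FEV1  % pred.  < 49
    c(95, 29, 0, 43, 43, 92, 90),      # FVC   % pred.  < 52
    c(93, 96, 100, 57, 63, 100, 100)   # N2    % pred.  > 478
  )
  colnames(m) <- c("specificity", "sensitivity_bos", "sensitivity_bos0p",
                   "ppv_bos", "ppv_bos_plus_0p", "npv_bos", "npv_bos_plus_0p")
  m
}

noiseless_config <- function(...) {
  cohort_config(measurement_cv = 0, seed = 5, ...)
}

default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(config = cohort_config(seed = 1))
    cache
  }
})

# independent least-squares fit used by slope oracles
lm_slope <- function(x, y) unname(coef(lm(y ~ x))[2])
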