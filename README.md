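# bosn2

Single-breath nitrogen washout analysis for bronchiolitis obliterans
surveillance after double lung and heart-lung transplantation.

## The problem

Bronchiolitis obliterans syndrome (BOS) — chronic allograft dysfunction from
progressive small-airway obstruction — is diagnosed functionally: a sustained
fall of FEV₁ to ≤ 80% of the post-transplant baseline (the baseline being the
mean of the two highest measurements ≥ 3 weeks apart, from 4.5 months
post-transplant), with a "potential BOS" stage (BOS 0-p) at 81–90%. Spirometry
reacts late. The alveolar (phase III) slope of the single-breath nitrogen
washout, in %N₂ per litre, measures ventilation inhomogeneity in exactly the
peripheral airways where the disease starts, and tends to rise **before** the
FEV₁ falls.

`bosn2` implements the full evaluation pipeline for this marker:

* **Slope extraction** — closing-point detection by exhaustive two-segment
  piecewise-linear least squares, then the alveolar slope over the window from
  TLC − 0.825 L to the closing point (`compute_n2_slope()`).
* **Normalisation** — percent of predicted normal (configurable reference
  equations) and percent of the patient's latest baseline
  (`normalize_cohort()`).
* **Staging** — BOS bands on FEV₁ percent-of-baseline with 3-week
  confirmation, onset dating, and terminal BOS 0-p handling
  (`stage_cohort()`).
* **Test evaluation** — cut-offs calibrated to 95% specificity on stable
  patients, per-measurement contingency counts by current diagnostic status,
  and operating characteristics (`calibrate_cutoff()`, `tabulate_counts()`,
  `operating_characteristics()`).
* **Predictive ability** — among abnormal results obtained *before* a BOS
  diagnosis, the percentage that precede a later diagnosis; for single tests
  and for the combined FEV₁ + N₂ criterion (`predictive_ability()`). This is
  deliberately not a conventional PPV, which would also count post-diagnosis
  results.
* **Synthetic cohorts** — a seeded generator emulating a three-year follow-up
  programme (61 recipients, visits at 1–36 months, ~15 BOS, 3 unresolved
  terminal BOS 0-p, N₂ rise leading the FEV₁ decline), so the whole pipeline
  is testable against known truth (`generate_cohort()`).

See `vignettes/bosn2-methods.Rmd` for the model, parameter and design
discussion.

## Worked example

Extract a slope from a (here synthetic, seeded) washout tracing:

```r
library(bosn2)
tr <- generate_washout_tracing(tracing_params(
  phase3_slope = 1.5, closing_volume = 0.9, phase4_slope = 6,
  noise_sd = 0.15, seed = 42))
compute_n2_slope(tr)
#> <n2_slope_result> slope 1.4883 %N2/L over [0.840, 3.620] L (140 samples), closing point 3.620 L
```

The true plateau slope is 1.5 %N₂/L and the true closing point 3.6 L expired:
both are recovered to within the noise floor (and exactly, on noiseless
tracings).

Operating characteristics from a contingency table of normal/abnormal results
binned by current status (NoBOS / BOS / BOS 0-p) — here the published counts
for the N₂-slope > 478% predicted cut-off:

```r
operating_characteristics(contingency_counts(234, 18, 1, 24, 0, 7))
#> <operating_characteristics>
#>       specificity   sensitivity_bos sensitivity_bos0p           ppv_bos
#>                93                96               100                57
#>   ppv_bos_plus_0p           npv_bos   npv_bos_plus_0p
#>                63               100               100
```

So the slope identified 96% of BOS visits and 100% of BOS 0-p visits, at 93%
specificity. The predictive ability of the combined criterion (FEV₁ < 90%
basal *and* N₂-slope > 478% predicted, published occasion counts):

```r
prediction_counts(259, 12, 9)
#> <prediction_counts> 259 results, 12 abnormal, 9 preceding BOS -> predictive value 75%
```

End to end on a synthetic cohort:

```r
b <- run_pipeline(config = cohort_config(seed = 1))
b$stage_table
#> # A tibble: 5 × 7
#>   stage   `6`   `9`  `12`  `18`  `24`  `36`
#>   <chr> <int> <int> <int> <int> <int> <int>
#> 1 NoBOS    58    51    49    46    42    38
#> 2 BOS0p     0     2     0     0     1     3
#> 3 BOS1      0     5     9     5     5     0
#> 4 BOS2      0     0     0     6     6     5
#> 5 BOS3      0     0     0     0     3     7
b$cutoffs[["N2_slope_pct_pred"]]
#> <cutoff_spec> N2_slope pct_pred > 320.6 (calibrated)
```

Column sums are the patients still in follow-up; BOS accrues and deepens over
time while BOS 0-p stays sparse, and the N₂ cut-off is calibrated on this
cohort's own stable patients (each synthetic cohort gets its own cut-off, just
as each real cohort should).

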