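#' Round half away from zero
#'
#' Rounding used for all reported percentages: halves round up (54.5 -> 55),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(54.5, 99.6, 26.67))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

config_error <- function(msg) {
  abort(msg, class = "bosn2_config_error")
}

analysis_error <- function(msg) {
  abort(msg, class = "bosn2_analysis_error")
}

validation_error <- function(msg) {
  abort(msg, class = "bosn2_validation_error")
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    config_error(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Measured lung-function variables
#'
#' Canonical variable names used throughout the package: forced expiratory
#' volume in 1 s (L), forced vital capacity (L), total lung capacity (L),
#' functional residual capacity (L), residual volume (L), carbon monoxide
#' uptake (mmol min^-1 kPa^-1) and the alveolar nitrogen slope (% N2 per L).
#'
#' @return Character vector of variable names.
#' @export
lung_function_variables <- function() {
  c("FEV1", "FVC", "TLC", "FRC", "RV", "CO_uptake", "N2_slope")
}
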