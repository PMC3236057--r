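#' Single-breath washout tracing
#'
#' Container for one single-breath nitrogen washout manoeuvre: expired volume
#' (L BTPS, 0 at the start of expiration, i.e. at total lung capacity) against
#' expired nitrogen concentration (% N2). Lung volume at any sample is
#' `tlc - expired_volume` when TLC is known.
#'
#' @param expired_volume Strictly increasing expired volumes in L, starting at
#'   (approximately) 0.
#' @param n2 Nitrogen concentrations in % N2, same length, within [0, 100].
#' @param vital_capacity Vital capacity in L BTPS; defaults to the last
#'   expired volume.
#' @param tlc Total lung capacity in L BTPS, or NULL when unknown.
#' @return An object of class `washout_tracing`.
#' @export
washout_tracing <- function(expired_volume, n2,
                            vital_capacity = max(expired_volume), tlc = NULL) {
  if (length(expired_volume) != length(n2)) {
    config_error("`expired_volume` and `n2` must have the same length")
  }
  if (length(expired_volume) < 2L) {
    config_error("a tracing needs at least two samples")
  }
  if (any(diff(expired_volume) <= 0)) {
    config_error("`expired_volume` must be strictly increasing")
  }
  if (any(n2 < 0 | n2 > 100)) {
    config_error("`n2` must lie within [0, 100] %")
  }
  structure(
    list(
      expired_volume = as.numeric(expired_volume),
      n2 = as.numeric(n2),
      vital_capacity = as.numeric(vital_capacity),
      tlc = if (is.null(tlc)) NULL else as.numeric(tlc)
    ),
    class = "washout_tracing"
  )
}

#' @export
print.washout_tracing <- function(x, ...) {
  cat(sprintf(
    "<washout_tracing> %d samples, VC %.2f L%s, N2 %.2f-%.2f %%\n",
    length(x$expired_volume), x$vital_capacity,
    if (is.null(x$tlc)) "" else sprintf(", TLC %.2f L", x$tlc),
    min(x$n2), max(x$n2)
  ))
  invisible(x)
}

#' Parameters of a synthetic washout tracing
#'
#' Defines a four-phase single-breath nitrogen washout waveform: phase I
#' (dead-space gas, ~0% N2), phase II (sigmoid bronchial-alveolar interface),
#' phase III (linear alveolar plateau) and phase IV (steeper rise after the
#' closing point where dependent airways close).
#'
#' @param vital_capacity Vital capacity, L BTPS.
#' @param tlc Total lung capacity, L BTPS.
#' @param dead_space Airway dead space emptied during phase I, L.
#' @param phase3_slope Alveolar plateau slope, % N2 per L.
#' @param closing_volume Volume above residual volume at which phase IV
#'   starts, L; phase IV begins at expired volume
#'   `vital_capacity - closing_volume`. Use 0 for no phase IV.
#' @param phase4_slope Phase IV slope, % N2 per L (>= `phase3_slope`).
#' @param n2_start Plateau concentration at the onset of phase III, % N2.
#' @param phase2_width Volume over which the phase II rise occurs, L.
#' @param noise_sd Additive Gaussian noise on concentrations, % N2.
#' @param sample_spacing Volume between successive samples, L.
#' @param seed Integer seed for the noise.
#' @return An object of class `tracing_params`.
#' @export
tracing_params <- function(vital_capacity = 4.5, tlc = 6.5, dead_space = 0.15,
                           phase3_slope = 1.5, closing_volume = 0.9,
                           phase4_slope = 6, n2_start = 25, phase2_width = 0.35,
                           noise_sd = 0.1, sample_spacing = 0.02, seed = 1L) {
  stopifnot_scalar_number(vital_capacity, "vital_capacity", min = 0.5)
  stopifnot_scalar_number(tlc, "tlc", min = vital_capacity)
  stopifnot_scalar_number(dead_space, "dead_space", min = 0)
  stopifnot_scalar_number(phase3_slope, "phase3_slope", min = 0)
  stopifnot_scalar_number(closing_volume, "closing_volume", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(sample_spacing, "sample_spacing")
  if (sample_spacing <= 0) config_error("`sample_spacing` must be > 0")
  if (closing_volume >= vital_capacity) {
    config_error("`closing_volume` must be smaller than `vital_capacity`")
  }
  if (phase4_slope < phase3_slope) {
    config_error("`phase4_slope` must be >= `phase3_slope`")
  }
  structure(
    list(
      vital_capacity = vital_capacity, tlc = tlc, dead_space = dead_space,
      phase3_slope = phase3_slope, closing_volume = closing_volume,
      phase4_slope = phase4_slope, n2_start = n2_start,
      phase2_width = phase2_width, noise_sd = noise_sd,
      sample_spacing = sample_spacing, seed = as.integer(seed)
    ),
    class = "tracing_params"
  )
}

# smoothstep: exactly 0 below 0, exactly 1 above 1, sigmoid in between.
# Exactness matters: the plateau of a noiseless synthetic tracing must be
# strictly linear so slope recovery can be checked to machine precision.
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate a synthetic single-breath washout tracing
#'
#' Builds the noiseless four-phase waveform described in [tracing_params()]
#' and adds seeded Gaussian noise. The phase III segment is exactly linear
#' (slope `phase3_slope`) and phase IV is exactly linear with slope
#' `phase4_slope` from expired volume `vital_capacity - closing_volume`.
#'
#' @param params A [tracing_params()] object.
#' @return A [washout_tracing()].
#' @export
#' @examples
#' tr <- generate_washout_tracing(tracing_params(noise_sd = 0, seed = 42))
#' range(tr$n2)
generate_washout_tracing <- function(params) {
  if (!inherits(params, "tracing_params")) {
    config_error("`params` must be a tracing_params object")
  }
  v <- seq(0, params$vital_capacity, by = params$sample_spacing)
  v2_start <- params$dead_space
  v3_start <- params$dead_space + params$phase2_width
  v4_start <- params$vital_capacity - params$closing_volume
  if (v3_start >= v4_start && params$closing_volume > 0) {
    config_error("phase III window is empty: dead_space + phase2_width must be < VC - closing_volume")
  }
  conc <- params$n2_start * smoothstep((v - v2_start) / (v3_start - v2_start)) +
    params$phase3_slope * pmax(0, v - v3_start) +
    (params$phase4_slope - params$phase3_slope) * pmax(0, v - v4_start)
  if (params$noise_sd > 0) {
    conc <- conc + with_seed(params$seed, rnorm(length(v), 0, params$noise_sd))
  }
  conc <- pmin(pmax(conc, 0), 100)
  washout_tracing(v, conc, vital_capacity = params$vital_capacity, tlc = params$tlc)
}

#' Write / read a washout tracing as two-column text
#'
#' The format is plain tab-separated text with metadata in `#` comment lines
#' (`vc`, `tlc`, `sample_spacing`) followed by a header and two numeric
#' columns `expired_volume_L` and `n2_percent`.
#'
#' @param tracing A [washout_tracing()].
#' @param path File path.
#' @return `write_tracing()` returns `path` invisibly; `read_tracing()`
#'   returns a [washout_tracing()].
#' @export
write_tracing <- function(tracing, path) {
  if (!inherits(tracing, "washout_tracing")) {
    config_error("`tracing` must be a washout_tracing")
  }
  spacing <- if (length(tracing$expired_volume) > 1) {
    min(diff(tracing$expired_volume))
  } else {
    NA_real_
  }
  meta <- c(
    sprintf("# vc=%.17g", tracing$vital_capacity),
    if (!is.null(tracing$tlc)) sprintf("# tlc=%.17g", tracing$tlc),
    sprintf("# sample_spacing=%.17g", spacing)
  )
  body <- paste(
    format(tracing$expired_volume, digits = 17, scientific = FALSE, trim = TRUE),
    format(tracing$n2, digits = 17, scientific = FALSE, trim = TRUE),
    sep = "\t"
  )
  writeLines(c(meta, "expired_volume_L\tn2_percent", body), path)
  invisible(path)
}

#' @rdname write_tracing
#' @export
read_tracing <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("tracing file not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), meta_lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    as.numeric(sub(sprintf("^#\\s*%s=", key), "", hit[1]))
  }
  dat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("expired_volume_L", "n2_percent") %in% names(dat))) {
    validation_error(sprintf("%s is not a two-column tracing file", path))
  }
  vc <- get_meta("vc")
  washout_tracing(
    dat$expired_volume_L, dat$n2_percent,
    vital_capacity = if (is.null(vc)) max(dat$expired_volume_L) else vc,
    tlc = get_meta("tlc")
  )
}
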