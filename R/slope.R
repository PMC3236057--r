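#' Configuration of the alveolar-slope algorithm
#'
#' The alveolar (phase III) slope is the difference in N2 concentration
#' between the closing point and the point 0.825 L BTPS below total lung
#' capacity, divided by the corresponding volume. With expired volume measured
#' from the start of expiration (at TLC), the proximal anchor sits at expired
#' volume `proximal_offset`; the offset excludes dead-space emptying and the
#' phase II front from the fitted window.
#'
#' @param proximal_offset Expired volume (L BTPS) at which the analysis window
#'   starts; default 0.825 L below TLC.
#' @param closing_detection Detection method tag; currently only
#'   `"two_segment"` (exhaustive two-segment piecewise-linear least squares).
#' @param min_window Minimum analysable window length in L; shorter tracings
#'   raise an analysis error.
#' @param slope_ratio A phase IV is declared only when the distal segment's
#'   slope exceeds the proximal segment's by this factor...
#' @param min_slope_gap ...and by at least this absolute amount (% N2 per L),
#'   guarding against noise-driven detections on plateaus with near-zero
#'   slope.
#' @return An object of class `slope_config`.
#' @export
slope_config <- function(proximal_offset = 0.825, closing_detection = "two_segment",
                         min_window = 0.3, slope_ratio = 2, min_slope_gap = 0.2) {
  if (proximal_offset <= 0) config_error("`proximal_offset` must be > 0")
  if (!identical(closing_detection, "two_segment")) {
    config_error(sprintf("unknown closing detection method: %s", closing_detection))
  }
  structure(
    list(proximal_offset = proximal_offset, closing_detection = closing_detection,
         min_window = min_window, slope_ratio = slope_ratio,
         min_slope_gap = min_slope_gap),
    class = "slope_config"
  )
}

# Least-squares slope and RSS for every contiguous index range, in O(1) per
# range after O(n) prefix sums.
segment_stats <- function(x, y) {
  list(
    n = length(x),
    sx = cumsum(x), sy = cumsum(y),
    sxx = cumsum(x * x), sxy = cumsum(x * y), syy = cumsum(y * y)
  )
}

range_sum <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0

segment_fit <- function(st, i, j) {
  n <- j - i + 1
  sx <- range_sum(st$sx, i, j)
  sy <- range_sum(st$sy, i, j)
  sxx <- range_sum(st$sxx, i, j)
  sxy <- range_sum(st$sxy, i, j)
  syy <- range_sum(st$syy, i, j)
  cxx <- sxx - sx * sx / n
  cxy <- sxy - sx * sy / n
  cyy <- syy - sy * sy / n
  slope <- cxy / cxx
  rss <- cyy - cxy * cxy / cxx
  list(slope = slope, intercept = (sy - slope * sx) / n, rss = max(rss, 0))
}

window_indices <- function(tracing, config) {
  idx <- which(tracing$expired_volume >= config$proximal_offset - 1e-12)
  if (length(idx) < 4L) {
    analysis_error("fewer than 4 samples beyond the proximal offset")
  }
  v <- tracing$expired_volume[idx]
  if (v[length(v)] - v[1] < config$min_window) {
    analysis_error(sprintf(
      "analysable window %.3f L is shorter than min_window %.3f L",
      v[length(v)] - v[1], config$min_window
    ))
  }
  idx
}

#' Detect the closing point (phase IV onset) of a washout tracing
#'
#' Scans every candidate breakpoint in the window from the proximal offset to
#' the end of expiration, fitting a separate least-squares line to the
#' proximal and distal sides, and takes the split with the smallest total
#' residual sum of squares. A phase IV is declared only when the distal slope
#' exceeds the proximal slope by both the configured ratio and absolute gap;
#' otherwise the closing point is reported at the end of expiration
#' (`vital_capacity`), i.e. no detectable airway closure.
#'
#' @param tracing A [washout_tracing()].
#' @param config A [slope_config()].
#' @return Expired volume (L) of the closing point.
#' @export
detect_closing_point <- function(tracing, config = slope_config()) {
  idx <- window_indices(tracing, config)
  v <- tracing$expired_volume[idx]
  y <- tracing$n2[idx]
  m <- length(v)
  st <- segment_stats(v, y)
  best_rss <- Inf
  best_k <- NA_integer_
  for (k in 2:(m - 2L)) {
    fit1 <- segment_fit(st, 1L, k)
    fit2 <- segment_fit(st, k + 1L, m)
    rss <- fit1$rss + fit2$rss
    if (rss < best_rss - 1e-15) {
      best_rss <- rss
      best_k <- k
    }
  }
  fit1 <- segment_fit(st, 1L, best_k)
  fit2 <- segment_fit(st, best_k + 1L, m)
  has_phase4 <- is.finite(fit2$slope) && is.finite(fit1$slope) &&
    fit2$slope > config$slope_ratio * fit1$slope &&
    fit2$slope - fit1$slope > config$min_slope_gap
  if (!has_phase4) {
    return(tracing$vital_capacity)
  }
  v[best_k]
}

#' Compute the alveolar (phase III) N2 slope of a tracing
#'
#' Fits a least-squares line over the window from the proximal offset (0.825 L
#' of expired volume by default) to the detected closing point. The slope of
#' that line equals the difference of the fitted N2 concentrations at the two
#' window endpoints divided by the volume between them; using the fitted line
#' rather than the two raw samples makes the estimate robust to sample noise
#' while agreeing exactly in the noiseless limit.
#'
#' @inheritParams detect_closing_point
#' @return An object of class `n2_slope_result`: `slope` (% N2 per L),
#'   `closing_point_volume` (L expired), `window` (start, end in L),
#'   `n_samples_used`.
#' @export
#' @examples
#' tr <- generate_washout_tracing(tracing_params(phase3_slope = 2, noise_sd = 0))
#' compute_n2_slope(tr)$slope
compute_n2_slope <- function(tracing, config = slope_config()) {
  cp <- detect_closing_point(tracing, config)
  idx <- window_indices(tracing, config)
  keep <- idx[tracing$expired_volume[idx] <= cp + 1e-12]
  if (length(keep) < 2L) {
    analysis_error("fewer than 2 samples between the proximal offset and the closing point")
  }
  v <- tracing$expired_volume[keep]
  y <- tracing$n2[keep]
  if (v[length(v)] - v[1] <= 0) {
    analysis_error("non-positive volume difference across the analysis window")
  }
  st <- segment_stats(v, y)
  fit <- segment_fit(st, 1L, length(v))
  structure(
    list(
      slope = fit$slope,
      closing_point_volume = cp,
      window = c(start = v[1], end = v[length(v)]),
      n_samples_used = length(v)
    ),
    class = "n2_slope_result"
  )
}

#' @export
print.n2_slope_result <- function(x, ...) {
  cat(sprintf(
    "<n2_slope_result> slope %.4f %%N2/L over [%.3f, %.3f] L (%d samples), closing point %.3f L\n",
    x$slope, x$window[1], x$window[2], x$n_samples_used, x$closing_point_volume
  ))
  invisible(x)
}

#' Average several acceptable recordings
#'
#' When two or more acceptable recordings of the same manoeuvre are obtained,
#' the reported slope is their arithmetic mean; the window and closing point
#' of the first recording are retained for the report.
#'
#' @param slopes A list of [compute_n2_slope()] results.
#' @return A single `n2_slope_result`.
#' @export
average_recordings <- function(slopes) {
  if (length(slopes) == 0L) analysis_error("no recordings supplied")
  if (!all(vapply(slopes, inherits, logical(1), "n2_slope_result"))) {
    config_error("`slopes` must be a list of n2_slope_result objects")
  }
  out <- slopes[[1]]
  out$slope <- mean(vapply(slopes, function(s) s$slope, numeric(1)))
  out
}
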