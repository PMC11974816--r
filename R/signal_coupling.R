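# Cross-correlation of cell-edge displacement with the near-edge reporter
# signal: lag analysis of edge dynamics vs signalling.

#' Near-edge signal time series from a ratio kymograph
#'
#' Per frame, the mean of the `n_pixels` interior-side kymograph pixels
#' immediately inside the traced edge position.
#'
#' @param kym [build_kymograph()] of the ratio channel.
#' @param trace [trace_edge()] result aligned to the same frames.
#' @param n_pixels number of interior pixels averaged (default 4).
#' @return Numeric series, one value per frame.
#' @export
near_edge_signal <- function(kym, trace, n_pixels = 4L) {
  n_t <- ncol(kym$values)
  if (nrow(trace) != n_t) stop("trace not aligned to kymograph frames")
  pos_px <- trace$position_um / kym$space_step_um
  out <- numeric(n_t)
  for (t in seq_len(n_t)) {
    hi <- floor(pos_px[t]) + 1L   # row index just inside the edge
    lo <- hi - n_pixels + 1L
    if (lo < 1L) stop("edge within n_pixels of the line's interior end")
    out[t] <- mean(kym$values[lo:hi, t])
  }
  out
}

#' Normalised cross-correlogram of edge motion and signal
#'
#' Both series are Gaussian-filtered (`presmooth_sigma` frames),
#' mean-subtracted and scaled to unit variance (biased, denominator `n`),
#' then correlated over lags up to `max_lag` frames. Positive lag means
#' the signal leads the edge: the coefficient at lag `k` is
#' `mean(edge(t + k) * signal(t))`.
#'
#' @param edge_series edge displacement (or velocity) per frame.
#' @param signal_series signal per frame; same length, >= 10 frames.
#' @param presmooth_sigma Gaussian sigma in frames (default 1).
#' @param frame_interval_s seconds per frame (lags are reported in s).
#' @param max_lag maximum lag in frames; defaults to `floor(n/3)`.
#' @return Object of class `CrossCorrelogram`: data frame fields
#'   `lag_frames`, `lags_s`, `coefficients`, plus `peak_lag_s`,
#'   `peak_coefficient` and metadata.
#' @export
cross_correlate <- function(edge_series, signal_series, presmooth_sigma = 1,
                            frame_interval_s = 1, max_lag = NULL) {
  n <- length(edge_series)
  if (length(signal_series) != n) stop("series lengths differ")
  if (n < 10L) stop("need >= 10 frames")
  e <- .gauss_smooth1d(as.numeric(edge_series), presmooth_sigma)
  s <- .gauss_smooth1d(as.numeric(signal_series), presmooth_sigma)
  if (sd(e) == 0 || sd(s) == 0) stop("zero-variance series")
  sd_b <- function(x) sqrt(mean((x - mean(x))^2))
  e <- (e - mean(e)) / sd_b(e)
  s <- (s - mean(s)) / sd_b(s)
  if (is.null(max_lag)) max_lag <- floor(n / 3)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(e[(1 + k):n] * s[1:(n - k)]) / n
    else sum(e[1:(n + k)] * s[(1 - k):n]) / n
  }, numeric(1))
  pk <- which.max(cc)
  structure(list(lag_frames = lags, lags_s = lags * frame_interval_s,
                 coefficients = cc,
                 peak_lag_s = lags[pk] * frame_interval_s,
                 peak_coefficient = cc[pk],
                 frame_interval_s = frame_interval_s,
                 smoothing = list(presmooth_sigma = presmooth_sigma)),
            class = "CrossCorrelogram")
}

#' @export
print.CrossCorrelogram <- function(x, ...) {
  cat(sprintf(
    "CrossCorrelogram: %d lags, peak %.3f at %+.4g s (signal leads edge at +)\n",
    length(x$lag_frames), x$peak_coefficient, x$peak_lag_s))
  invisible(x)
}

#' Spline-smooth a cross-correlogram
#'
#' Fits a cubic smoothing spline to the coefficients and relocates the
#' peak as the argmax of the spline evaluated on a 10x-refined lag grid.
#' `smoothing_factor = 0` gives an interpolating spline (values preserved
#' at the knots).
#'
#' @param cc a [cross_correlate()] result with >= 5 lags.
#' @param smoothing_factor smoothing parameter in `[0, 1]`, mapped to
#'   `smooth.spline`'s `spar`.
#' @return The correlogram with `smoothed` values, refined `peak_lag_s`,
#'   and a `smoothing` description added.
#' @export
smooth_correlogram <- function(cc, smoothing_factor = 0.5) {
  stopifnot(inherits(cc, "CrossCorrelogram"))
  x <- cc$lag_frames
  if (length(x) < 5L) stop("need >= 5 lags")
  fine <- seq(min(x), max(x), length.out = (length(x) - 1L) * 10L + 1L)
  if (smoothing_factor <= 0) {
    f <- splinefun(x, cc$coefficients, method = "natural")
    sm_at_knots <- cc$coefficients
    sm_fine <- f(fine)
  } else {
    fit <- smooth.spline(x, cc$coefficients, spar = smoothing_factor)
    sm_at_knots <- predict(fit, x)$y
    sm_fine <- predict(fit, fine)$y
  }
  pk <- which.max(sm_fine)
  cc$smoothed <- sm_at_knots
  cc$peak_lag_s <- fine[pk] * cc$frame_interval_s
  cc$peak_coefficient <- sm_fine[pk]
  cc$smoothing <- c(cc$smoothing,
                    list(spline = "cubic", factor = smoothing_factor))
  cc
}

#' Edge-signal lag analysis of an edge movie
#'
#' Convenience chain: kymograph on the given line, edge tracing,
#' near-edge signal extraction, cross-correlation (displacement by
#' default, velocity optional) and spline smoothing.
#'
#' @param stack single- or multi-channel [channel_stack()].
#' @param channel ratio channel name or index.
#' @param p0,p1 kymograph line endpoints (row, col), interior first.
#' @param width_px kymograph averaging width.
#' @param n_pixels near-edge pixels averaged.
#' @param series correlate `"displacement"` (default) or `"velocity"`.
#' @param presmooth_sigma Gaussian sigma (frames) before correlation.
#' @param smoothing_factor spline smoothing factor; `NA` skips smoothing.
#' @return List with `kymograph`, `trace`, `signal`, `correlogram`.
#' @export
edge_signal_coupling <- function(stack, channel = 1L, p0, p1, width_px = 3L,
                                 n_pixels = 4L,
                                 series = c("displacement", "velocity"),
                                 presmooth_sigma = 1,
                                 smoothing_factor = 0.3) {
  series <- match.arg(series)
  kym <- build_kymograph(stack, channel, p0, p1, width_px)
  trace <- trace_edge(kym)
  sig <- near_edge_signal(kym, trace, n_pixels)
  edge <- if (series == "displacement") {
    trace$position_um
  } else {
    trace$velocity_um_min
  }
  cc <- cross_correlate(edge, sig, presmooth_sigma,
                        frame_interval_s = kym$time_step_s)
  if (!is.na(smoothing_factor)) cc <- smooth_correlogram(cc, smoothing_factor)
  list(kymograph = kym, trace = trace, signal = sig, correlogram = cc)
}
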