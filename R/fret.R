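# Spectral bleed-through calibration and corrected FRET efficiency maps.
#
# Correction model per pixel (all channels background-subtracted first):
#   corrected efficiency = (FRETraw - alpha * donor - beta * acceptor) / donor
# where alpha is the donor-to-FRET and beta the acceptor-to-FRET
# bleed-through fraction, measured on single-fluorophore cells.

#' Bleed-through calibration container
#'
#' @param alpha donor-to-FRET bleed-through fraction in `[0, 1)`.
#' @param beta acceptor-to-FRET bleed-through fraction in `[0, 1)`.
#' @param fit_diagnostics optional list of residual summaries.
#' @return An object of class `FretCalibration`.
#' @export
fret_calibration <- function(alpha = NA_real_, beta = NA_real_,
                             fit_diagnostics = list()) {
  for (v in c(alpha = alpha, beta = beta)) {
    if (!is.na(v) && (v < 0 || v >= 1)) {
      stop("bleed-through coefficients must lie in [0, 1)")
    }
  }
  structure(list(alpha = alpha, beta = beta,
                 fit_diagnostics = fit_diagnostics),
            class = "FretCalibration")
}

#' @export
print.FretCalibration <- function(x, ...) {
  cat(sprintf("FretCalibration: alpha = %.5g, beta = %.5g\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Estimate a bleed-through coefficient from a single-fluorophore stack
#'
#' Pools background-subtracted in-mask pixels across frames and fits a
#' zero-intercept linear model of FRET-channel intensity against the
#' fluorophore channel. The fit discards pixels outside the 1st-99th
#' percentile of fluorophore intensity to guard against hot pixels. A
#' negative slope is clamped to 0 with a warning.
#'
#' @param single_fluorophore_stack [channel_stack()] from cells expressing
#'   only the donor (or only the acceptor), containing that fluorophore
#'   channel and the FRET channel.
#' @param which `"donor"` or `"acceptor"`: which coefficient to estimate.
#' @param fluor_channel,fret_channel channel names; defaults `"mTFP1"` /
#'   `"mVenus"` and `"FRET"`.
#' @param mask optional [binary_mask()]; segmented from the fluorophore
#'   channel of frame 1 when absent.
#' @param subtract_bg subtract per-frame Otsu-median background first.
#' @return A `FretCalibration` with the estimated coefficient filled in
#'   and fit diagnostics (`n_pixels`, `residual_sd`, `slope`).
#' @export
estimate_bleedthrough <- function(single_fluorophore_stack,
                                  which = c("donor", "acceptor"),
                                  fluor_channel = NULL,
                                  fret_channel = "FRET", mask = NULL,
                                  subtract_bg = TRUE) {
  which <- match.arg(which)
  stack <- single_fluorophore_stack
  stopifnot(inherits(stack, "ChannelStack"))
  if (is.null(fluor_channel)) {
    fluor_channel <- if (which == "donor") "mTFP1" else "mVenus"
  }
  n_t <- dim(stack$pixels)[1L]
  if (is.null(mask)) {
    mask <- make_cell_mask(get_frame(stack, 1L, fluor_channel),
                           pixel_size_um = stack$pixel_size_um)
  }
  # background region: below the Otsu threshold AND clear of the dilated
  # cell mask, so dim cell-edge pixels cannot inflate the background
  # median of the FRET channel
  dil <- as.matrix(EBImage::dilate(EBImage::Image(mask$pixels * 1),
                                   EBImage::makeBrush(7L, "disc"))) > 0
  xs <- numeric(0); ys <- numeric(0)
  for (t in seq_len(n_t)) {
    fl <- get_frame(stack, t, fluor_channel)
    fr <- get_frame(stack, t, fret_channel)
    if (subtract_bg) {
      thr <- .otsu_threshold(fl)
      bg_region <- fl < thr & !dil
      if (!any(bg_region)) bg_region <- fl < thr
      # no clipping here: zero-mean residual noise must stay zero-mean
      # or the zero-intercept slope acquires a positive bias
      fl <- fl - median(fl[bg_region])
      fr <- fr - median(fr[bg_region])
    }
    xs <- c(xs, fl[mask$pixels])
    ys <- c(ys, fr[mask$pixels])
  }
  if (length(xs) < 100L) stop("need >= 100 in-mask pixels for calibration")
  q <- quantile(xs, c(0.01, 0.99))
  keep <- xs >= q[1L] & xs <= q[2L] & xs > 0
  xs <- xs[keep]; ys <- ys[keep]
  slope <- sum(xs * ys) / sum(xs * xs)
  if (slope < 0) {
    warning("negative fitted bleed-through slope; clamped to 0")
    slope <- 0
  }
  diag <- list(n_pixels = length(xs), slope = slope,
               residual_sd = sd(ys - slope * xs))
  if (which == "donor") {
    fret_calibration(alpha = slope, fit_diagnostics = diag)
  } else {
    fret_calibration(beta = slope, fit_diagnostics = diag)
  }
}

#' Bleed-through-corrected FRET efficiency map
#'
#' Applies, per pixel, `(fret_raw - alpha * donor - beta * acceptor) /
#' donor` inside the mask. Pixels whose donor intensity falls below an
#' adaptive guard (`1e-6 x` in-mask median donor) are flagged `NA`.
#'
#' @param fret_raw,donor,acceptor background-subtracted, registered 2-D
#'   matrices of equal size.
#' @param cal a [fret_calibration()] with both coefficients set.
#' @param mask a [binary_mask()] of the cell.
#' @return Object of class `FretEfficiencyMap` with fields `pixels`
#'   (NA outside mask), `mask`, `calibration`.
#' @export
corrected_fret_map <- function(fret_raw, donor, acceptor, cal, mask) {
  stopifnot(inherits(cal, "FretCalibration"))
  if (is.na(cal$alpha) || is.na(cal$beta)) {
    stop("calibration must provide both alpha and beta")
  }
  if (!all(dim(fret_raw) == dim(donor)) ||
      !all(dim(fret_raw) == dim(acceptor)) ||
      !all(dim(fret_raw) == dim(mask$pixels))) {
    stop("shape mismatch")
  }
  eps <- 1e-6 * median(donor[mask$pixels])
  ok <- mask$pixels & donor > max(eps, .Machine$double.eps)
  px <- matrix(NA_real_, nrow(fret_raw), ncol(fret_raw))
  px[ok] <- (fret_raw[ok] - cal$alpha * donor[ok] -
               cal$beta * acceptor[ok]) / donor[ok]
  structure(list(pixels = px, mask = mask, calibration = cal),
            class = "FretEfficiencyMap")
}

#' Lamellipodia-to-cell-body FRET efficiency ratio
#'
#' @param map a `FretEfficiencyMap` (or `RatioMap`).
#' @param lp_mask,cb_mask disjoint, non-empty [binary_mask()]s for the
#'   lamellipodium and the cell body.
#' @return Mean efficiency in `lp_mask` divided by mean in `cb_mask`.
#' @export
lp_to_cb_fret <- function(map, lp_mask, cb_mask) {
  lp <- lp_mask$pixels; cb <- cb_mask$pixels
  if (!any(lp) || !any(cb)) stop("empty LP or CB mask")
  if (any(lp & cb)) stop("LP and CB masks overlap")
  mean(map$pixels[lp], na.rm = TRUE) / mean(map$pixels[cb], na.rm = TRUE)
}

#' Mean value versus distance from the cell edge
#'
#' Bins in-mask pixels by Euclidean distance to a polyline on the cell
#' edge and returns the per-bin mean and standard error, i.e. a line
#' profile across the edge.
#'
#' @param map a `FretEfficiencyMap` or `RatioMap`.
#' @param edge_curve n x 2 matrix of (row, col) vertices along the edge.
#' @param depth_um maximum distance from the edge (> 0).
#' @param bin_um bin width (> 0).
#' @param pixel_size_um micrometres per pixel.
#' @return Data frame `distance_um` (bin midpoints), `mean`, `se`, `n`;
#'   empty bins carry `NA` means and `n = 0`.
#' @export
edge_line_profile <- function(map, edge_curve, depth_um, bin_um,
                              pixel_size_um = map$mask$pixel_size_um) {
  if (depth_um <= 0 || bin_um <= 0) stop("depth_um and bin_um must be > 0")
  edge_curve <- as.matrix(edge_curve)
  if (nrow(edge_curve) < 2L) stop("edge_curve needs >= 2 vertices")
  mask <- map$mask$pixels
  idx <- which(mask & is.finite(map$pixels))
  h <- nrow(mask)
  pr <- ((idx - 1L) %% h) + 1L
  pc <- ((idx - 1L) %/% h) + 1L
  dmin <- rep(Inf, length(idx))
  for (s in seq_len(nrow(edge_curve) - 1L)) {
    p0 <- edge_curve[s, ]; p1 <- edge_curve[s + 1L, ]
    vx <- p1[1L] - p0[1L]; vy <- p1[2L] - p0[2L]
    len2 <- vx^2 + vy^2
    tt <- if (len2 > 0) {
      pmin(1, pmax(0, ((pr - p0[1L]) * vx + (pc - p0[2L]) * vy) / len2))
    } else 0
    d <- sqrt((pr - (p0[1L] + tt * vx))^2 + (pc - (p0[2L] + tt * vy))^2)
    dmin <- pmin(dmin, d)
  }
  dist_um <- dmin * pixel_size_um
  edges <- seq(0, depth_um, by = bin_um)
  if (edges[length(edges)] < depth_um) edges <- c(edges, depth_um)
  bin <- cut(dist_um, edges, include.lowest = TRUE)
  vals <- map$pixels[idx]
  agg_mean <- tapply(vals, bin, mean)
  agg_sd <- tapply(vals, bin, sd)
  agg_n <- tapply(vals, bin, length)
  agg_n[is.na(agg_n)] <- 0L
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  data.frame(distance_um = mids,
             mean = as.numeric(agg_mean),
             se = as.numeric(agg_sd) / sqrt(pmax(as.numeric(agg_n), 1)),
             n = as.integer(agg_n))
}
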