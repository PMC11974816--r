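# Ratiometric reporter/reference mapping: shading correction, drift
# registration, Otsu background subtraction, denoising, ratio and masking.

#' Flat-field (shading) correction
#'
#' Divides every channel by its cell-free blank image, normalised to unit
#' mean, so that overall intensity scale is preserved. A single blank is
#' recycled across channels; a list supplies one blank per channel.
#'
#' @param stack a [channel_stack()].
#' @param reference_blank matrix, or list of matrices (one per channel).
#' @param blank_smooth_sigma optional Gaussian smoothing (px) applied to
#'   the blank before use; 0 disables.
#' @return Corrected [channel_stack()].
#' @export
shading_correct <- function(stack, reference_blank, blank_smooth_sigma = 0) {
  stopifnot(inherits(stack, "ChannelStack"))
  d <- dim(stack$pixels)
  if (!is.list(reference_blank)) {
    reference_blank <- rep(list(reference_blank), d[2L])
  }
  if (length(reference_blank) != d[2L]) {
    stop("need one blank per channel (or a single shared blank)")
  }
  out <- stack
  for (ch in seq_len(d[2L])) {
    blank <- .gauss_blur2d(as.matrix(reference_blank[[ch]]),
                           blank_smooth_sigma)
    if (any(blank <= 0)) {
      stop("blank image must be strictly positive after smoothing")
    }
    blank <- blank / mean(blank)
    for (t in seq_len(d[1L])) {
      out$pixels[t, ch, , ] <- stack$pixels[t, ch, , ] / blank
    }
  }
  out
}

# Phase-correlation shift estimate: returns (drow, dcol) such that
# `moving` is approximately `reference` shifted by that amount.
.phase_correlate <- function(reference, moving, subpixel = TRUE) {
  F1 <- stats::fft(reference)
  F2 <- stats::fft(moving)
  R <- F1 * Conj(F2)
  mag <- Mod(R)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(stats::fft(R / mag, inverse = TRUE))
  h <- nrow(r); w <- ncol(r)
  pk <- which.max(r)
  pr <- ((pk - 1L) %% h) + 1L
  pc <- ((pk - 1L) %/% h) + 1L
  # parabolic sub-pixel refinement around the (wrapped) peak
  off <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  dr <- off(pr, h); dc <- off(pc, w)
  if (subpixel) {
    wrap <- function(i, n) ((i - 1L) %% n) + 1L
    p3 <- function(vm, v0, vp) {
      den <- vm - 2 * v0 + vp
      if (abs(den) < .Machine$double.eps) 0 else 0.5 * (vm - vp) / den
    }
    dr <- dr + p3(r[wrap(pr - 1L, h), pc], r[pr, pc], r[wrap(pr + 1L, h), pc])
    dc <- dc + p3(r[pr, wrap(pc - 1L, w)], r[pr, pc], r[pr, wrap(pc + 1L, w)])
  }
  c(-dr, -dc)
}

# Translate a matrix by a (possibly fractional) displacement, bilinear.
.translate <- function(m, drow, dcol, fill = 0) {
  if (abs(drow - round(drow)) < 1e-9 && abs(dcol - round(dcol)) < 1e-9) {
    return(.shift_int(m, round(drow), round(dcol), fill))
  }
  h <- nrow(m); w <- ncol(m)
  rows <- matrix(seq_len(h), h, w) - drow
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - dcol
  matrix(.bilinear(m, as.numeric(rows), as.numeric(cols), fill), h, w)
}

#' Register movie frames onto the first frame
#'
#' Rigid translation estimated by phase correlation on `channel` (default:
#' the last channel, conventionally the structural/reference one), applied
#' to all channels. The `dense-flow` mode estimates a per-tile translation
#' field (phase correlation on overlapping tiles, bilinearly interpolated
#' per pixel) for slowly varying non-rigid drift.
#'
#' @param stack a [channel_stack()] with >= 1 frame.
#' @param method `"translation"` (default) or `"dense-flow"`.
#' @param channel channel used for estimation (name or index).
#' @param tiles tile grid (per side) for `dense-flow`.
#' @return List with `stack` (registered) and `displacements` (n_frames x 2
#'   matrix of estimated (row, col) shifts relative to frame 1; for
#'   `dense-flow` the tile-averaged shift).
#' @export
register_frames <- function(stack, method = c("translation", "dense-flow"),
                            channel = NULL, tiles = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "ChannelStack"))
  d <- dim(stack$pixels)
  if (d[1L] < 1L) stop("empty stack")
  if (is.null(channel)) channel <- d[2L]
  if (is.character(channel)) channel <- match(channel, stack$channel_names)
  disp <- matrix(0, d[1L], 2L,
                 dimnames = list(NULL, c("drow_px", "dcol_px")))
  if (d[1L] == 1L) return(list(stack = stack, displacements = disp))
  ref_img <- stack$pixels[1L, channel, , ]
  out <- stack
  for (t in 2:d[1L]) {
    mov <- stack$pixels[t, channel, , ]
    if (method == "translation") {
      sh <- .phase_correlate(ref_img, mov)
      disp[t, ] <- sh
      for (ch in seq_len(d[2L])) {
        out$pixels[t, ch, , ] <- .translate(stack$pixels[t, ch, , ],
                                            -sh[1L], -sh[2L])
      }
    } else {
      flow <- .dense_flow(ref_img, mov, tiles)
      disp[t, ] <- c(mean(flow$drow), mean(flow$dcol))
      for (ch in seq_len(d[2L])) {
        out$pixels[t, ch, , ] <- .warp_flow(stack$pixels[t, ch, , ], flow)
      }
    }
  }
  list(stack = out, displacements = disp)
}

# Per-pixel displacement field from per-tile phase correlation.
.dense_flow <- function(reference, moving, tiles = 3L) {
  h <- nrow(reference); w <- ncol(reference)
  rb <- round(seq(1, h + 1, length.out = tiles + 1L))
  cb <- round(seq(1, w + 1, length.out = tiles + 1L))
  cr <- numeric(0); cc <- numeric(0); vr <- numeric(0); vc <- numeric(0)
  for (i in seq_len(tiles)) for (j in seq_len(tiles)) {
    rs <- rb[i]:(rb[i + 1L] - 1L); cs <- cb[j]:(cb[j + 1L] - 1L)
    sh <- .phase_correlate(reference[rs, cs], moving[rs, cs])
    cr <- c(cr, mean(rs)); cc <- c(cc, mean(cs))
    vr <- c(vr, sh[1L]); vc <- c(vc, sh[2L])
  }
  grid_r <- matrix(seq_len(h), h, w)
  grid_c <- matrix(seq_len(w), h, w, byrow = TRUE)
  interp <- function(v) {
    zm <- matrix(v, tiles, tiles, byrow = TRUE)
    ur <- sort(unique(cr)); uc <- sort(unique(cc))
    ri <- pmin(pmax((grid_r - ur[1]) / diff(range(ur)) * (tiles - 1L) + 1, 1),
               tiles)
    ci <- pmin(pmax((grid_c - uc[1]) / diff(range(uc)) * (tiles - 1L) + 1, 1),
               tiles)
    matrix(.bilinear(zm, as.numeric(ri), as.numeric(ci)), h, w)
  }
  list(drow = interp(vr), dcol = interp(vc))
}

.warp_flow <- function(m, flow) {
  h <- nrow(m); w <- ncol(m)
  rows <- matrix(seq_len(h), h, w) + flow$drow
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) + flow$dcol
  matrix(.bilinear(m, as.numeric(rows), as.numeric(cols)), h, w)
}

#' Otsu-based background subtraction
#'
#' Background pixels are those below the Otsu threshold of the image; the
#' median intensity of the background pixels is subtracted from the whole
#' image and negative values are clipped to zero.
#'
#' @param image 2-D intensity matrix with >= 2 distinct values.
#' @return List with `image` (corrected) and `background_level` (the
#'   subtracted median).
#' @export
subtract_background <- function(image) {
  thr <- .otsu_threshold(image)  # errors on constant input
  bg <- image[image < thr]
  if (length(bg) == 0L) bg <- min(image)
  level <- median(bg)
  list(image = pmax(image - level, 0), background_level = level)
}

#' Segment the cell footprint from a structural channel
#'
#' Otsu threshold, hole filling, then retention of the largest connected
#' component.
#'
#' @param structural_channel 2-D intensity matrix.
#' @param min_object_px smallest acceptable component area, px.
#' @param pixel_size_um calibration stored on the mask.
#' @return A [binary_mask()].
#' @export
make_cell_mask <- function(structural_channel, min_object_px = 50,
                           pixel_size_um = 1) {
  thr <- .otsu_threshold(structural_channel)
  fg <- structural_channel > thr
  fg <- as.matrix(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  lab <- .label_components(fg, 4L)
  if (max(lab) == 0L) stop("no foreground component found")
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_object_px) {
    stop("no foreground component >= min_object_px")
  }
  keep <- which.max(sizes)
  binary_mask(lab == keep, pixel_size_um)
}

#' Per-pixel reporter/reference ratio map
#'
#' Both channels are Gaussian-denoised (`denoise_sigma`), divided, and
#' restricted to the cell mask. Pixels outside the mask, or where the
#' denominator falls below an adaptive guard
#' (`1e-6 x` in-mask median of the reference), are flagged `NA`.
#'
#' @param reporter,reference background-subtracted 2-D matrices of equal
#'   size.
#' @param mask a [binary_mask()] of the cell.
#' @param denoise_sigma Gaussian sigma in px (default 0.5; 0 disables).
#' @param frame_index frame label stored on the result.
#' @return An object of class `RatioMap` with fields `pixels` (NA outside
#'   the mask), `frame_index`, `mask`.
#' @export
ratio_map <- function(reporter, reference, mask, denoise_sigma = 0.5,
                      frame_index = 1L) {
  if (!all(dim(reporter) == dim(reference))) stop("shape mismatch")
  if (!all(dim(reporter) == dim(mask$pixels))) stop("mask shape mismatch")
  rep_s <- .gauss_blur2d(reporter, denoise_sigma)
  ref_s <- .gauss_blur2d(reference, denoise_sigma)
  eps <- 1e-6 * median(ref_s[mask$pixels])
  ok <- mask$pixels & ref_s > max(eps, .Machine$double.eps)
  px <- matrix(NA_real_, nrow(reporter), ncol(reporter))
  px[ok] <- rep_s[ok] / ref_s[ok]
  structure(list(pixels = px, frame_index = frame_index, mask = mask),
            class = "RatioMap")
}

#' Edge-to-body ratio of a masked map
#'
#' Mean value within the edge band (pixels whose distance to the mask
#' boundary is at most `edge_depth_um`) divided by the mean over the
#' remaining cell-body pixels.
#'
#' @param map a `RatioMap` (or `FretEfficiencyMap`).
#' @param edge_depth_um band depth in micrometres.
#' @param pixel_size_um micrometres per pixel (defaults to the mask's).
#' @return A single ratio.
#' @export
edge_body_ratio <- function(map, edge_depth_um,
                            pixel_size_um = map$mask$pixel_size_um) {
  if (edge_depth_um <= 0) stop("edge_depth_um must be > 0")
  mask <- map$mask$pixels
  if (!any(mask)) stop("empty mask")
  d <- .distance_to_boundary(mask)
  # tolerance guards against e.g. 2.4/0.4 = 5.999... excluding the 6 px ring
  depth_px <- edge_depth_um / pixel_size_um * (1 + 1e-9)
  band <- mask & d <= depth_px
  body <- mask & d > depth_px
  if (!any(band) || !any(body)) {
    stop("edge band or cell body empty; check edge_depth_um")
  }
  mean(map$pixels[band], na.rm = TRUE) / mean(map$pixels[body], na.rm = TRUE)
}

#' Full ratiometric chain on a movie
#'
#' Applies, in order: shading correction (if a blank is given), rigid
#' registration onto frame 1, per-frame Otsu background subtraction (the
#' background region is found on `otsu_channel` and each channel subtracts
#' the median of its own pixels in that region), cell-mask segmentation
#' from `structural_channel`, Gaussian denoising and ratioing.
#'
#' @param stack two-channel [channel_stack()].
#' @param reporter,reference channel names.
#' @param blank optional cell-free blank image (or list per channel).
#' @param structural_channel channel used for the cell mask.
#' @param otsu_channel channel whose Otsu threshold defines the background
#'   region (`"reference"` by default).
#' @param denoise_sigma Gaussian sigma passed to [ratio_map()].
#' @param register logical; skip registration when `FALSE`.
#' @param edge_depth_um band depth for the per-frame edge/body ratio.
#' @return List with `maps` (list of `RatioMap`), `edge_body` (data frame
#'   `frame`, `edge_body_ratio`), `displacements`, `background_levels`.
#' @export
process_ratiometric_movie <- function(stack, reporter = "reporter",
                                      reference = "reference", blank = NULL,
                                      structural_channel = reference,
                                      otsu_channel = reference,
                                      denoise_sigma = 0.5, register = TRUE,
                                      edge_depth_um = 2.4) {
  stopifnot(inherits(stack, "ChannelStack"))
  if (!is.null(blank)) stack <- shading_correct(stack, blank)
  disp <- NULL
  if (register && dim(stack$pixels)[1L] > 1L) {
    reg <- register_frames(stack, channel = otsu_channel)
    stack <- reg$stack
    disp <- reg$displacements
  }
  n_t <- dim(stack$pixels)[1L]
  maps <- vector("list", n_t)
  bg <- matrix(NA_real_, n_t, 2L,
               dimnames = list(NULL, c(reporter, reference)))
  eb <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    ref_img <- get_frame(stack, t, reference)
    rep_img <- get_frame(stack, t, reporter)
    thr <- .otsu_threshold(get_frame(stack, t, otsu_channel))
    bg_region <- get_frame(stack, t, otsu_channel) < thr
    bg_rep <- median(rep_img[bg_region])
    bg_ref <- median(ref_img[bg_region])
    rep_img <- pmax(rep_img - bg_rep, 0)
    ref_img <- pmax(ref_img - bg_ref, 0)
    bg[t, ] <- c(bg_rep, bg_ref)
    mask <- make_cell_mask(get_frame(stack, t, structural_channel),
                           pixel_size_um = stack$pixel_size_um)
    maps[[t]] <- ratio_map(rep_img, ref_img, mask, denoise_sigma,
                           frame_index = t)
    eb[t] <- edge_body_ratio(maps[[t]], edge_depth_um)
  }
  list(maps = maps,
       edge_body = data.frame(frame = seq_len(n_t), edge_body_ratio = eb),
       displacements = disp, background_levels = bg)
}
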