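# Synthetic-data generators. Every generator returns its inputs and the
# quantities the analysis stages are supposed to recover ("ground truth"),
# and is deterministic given `seed`.

.new_ground_truth <- function(...) {
  structure(list(...), class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth with fields:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# Cell footprint: disc plus a half-elliptical lobe protruding in the +col
# direction, giving a well-defined free edge for kymograph lines.
.cell_footprint <- function(shape, center = NULL, radius = NULL) {
  h <- shape[1L]; w <- shape[2L]
  if (is.null(center)) center <- c(h / 2, w * 0.4)
  if (is.null(radius)) radius <- min(h, w) * 0.28
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  disc <- ((rows - center[1L])^2 + (cols - center[2L])^2) <= radius^2
  # lobe: outward half of an ellipse centred on the disc rim
  lc <- c(center[1L], center[2L] + radius)
  a_r <- radius * 0.7; a_c <- radius * 0.8
  lobe <- (((rows - lc[1L]) / a_r)^2 + ((cols - lc[2L]) / a_c)^2) <= 1 &
    cols >= lc[2L] - a_c * 0.2
  disc | lobe
}

.distance_to_boundary <- function(mask) {
  as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
}

#' Simulate a two-channel ratiometric reporter movie
#'
#' Generates a reporter/reference pair over a cell-shaped footprint whose
#' true per-pixel ratio is `gradient_peak` inside an edge band of depth
#' `edge_depth_px` and `body_ratio` in the remaining cell body, emulating a
#' front-enriched calcium reporter. Both channels are multiplied by a
#' smooth unit-mean shading field, shifted by a per-frame rigid drift, and
#' corrupted by additive Gaussian noise; a constant camera floor
#' (`background_level`) is present everywhere.
#'
#' @param shape `(rows, cols)` image size in px.
#' @param n_frames number of timepoints.
#' @param gradient_peak true ratio inside the edge band; must be >=
#'   `body_ratio`.
#' @param body_ratio true ratio in the cell body (> 0).
#' @param shading_amplitude relative amplitude of the multiplicative
#'   shading bump (0 = flat illumination).
#' @param drift_px_per_frame integer `(row, col)` rigid drift per frame.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed.
#' @param edge_depth_px depth of the high-ratio edge band, px.
#' @param ref_level reference-channel intensity inside the cell.
#' @param background_level camera floor added everywhere.
#' @param pixel_size_um,frame_interval_s calibration of the output stack.
#' @return A list with `stack` (a [channel_stack()] with channels
#'   `reporter`, `reference`) and `truth` (a `GroundTruth` carrying
#'   `true_ratio_map`, the footprint mask, the shading field and all
#'   generating parameters).
#' @export
simulate_ratiometric_movie <- function(shape = c(128L, 128L), n_frames = 5L,
                                       gradient_peak = 1.5, body_ratio = 1.0,
                                       shading_amplitude = 0,
                                       drift_px_per_frame = c(0L, 0L),
                                       noise_sd = 0, seed = 1L,
                                       edge_depth_px = 6,
                                       ref_level = 1000,
                                       background_level = 20,
                                       pixel_size_um = 0.4,
                                       frame_interval_s = 10) {
  if (any(shape <= 0) || n_frames < 1) stop("non-positive dimensions")
  if (gradient_peak < body_ratio || body_ratio <= 0) {
    stop("gradient_peak must be >= body_ratio > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  h <- shape[1L]; w <- shape[2L]
  mask <- .cell_footprint(shape)
  d <- .distance_to_boundary(mask)
  ratio <- matrix(NA_real_, h, w)
  ratio[mask] <- ifelse(d[mask] <= edge_depth_px, gradient_peak, body_ratio)

  shading <- .shading_field(shape, shading_amplitude)

  reference0 <- matrix(0, h, w); reference0[mask] <- ref_level
  reporter0 <- matrix(0, h, w); reporter0[mask] <- ratio[mask] * ref_level

  px <- array(0, dim = c(n_frames, 2L, h, w))
  for (t in seq_len(n_frames)) {
    dr <- round(drift_px_per_frame[1L] * (t - 1L))
    dc <- round(drift_px_per_frame[2L] * (t - 1L))
    rep_t <- (.shift_int(reporter0, dr, dc) + background_level) *
      .shift_int(shading, dr, dc, fill = 1)
    ref_t <- (.shift_int(reference0, dr, dc) + background_level) *
      .shift_int(shading, dr, dc, fill = 1)
    if (noise_sd > 0) {
      rep_t <- rep_t + matrix(rnorm(h * w, sd = noise_sd), h, w)
      ref_t <- ref_t + matrix(rnorm(h * w, sd = noise_sd), h, w)
    }
    px[t, 1L, , ] <- pmax(rep_t, 0)
    px[t, 2L, , ] <- pmax(ref_t, 0)
  }
  stack <- channel_stack(px, c("reporter", "reference"),
                         pixel_size_um, frame_interval_s)
  truth <- .new_ground_truth(
    true_ratio_map = ratio, footprint = mask, shading_field = shading,
    edge_depth_px = edge_depth_px, gradient_peak = gradient_peak,
    body_ratio = body_ratio, drift_px_per_frame = drift_px_per_frame,
    background_level = background_level, ref_level = ref_level,
    noise_sd = noise_sd, seed = seed)
  list(stack = stack, truth = truth)
}

# Smooth multiplicative illumination bump, normalised to unit mean so that
# flat-field division restores intensities exactly.
.shading_field <- function(shape, amplitude) {
  h <- shape[1L]; w <- shape[2L]
  if (amplitude == 0) return(matrix(1, h, w))
  rows <- matrix(seq_len(h), h, w) / h
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  f <- 1 + amplitude * exp(-(((rows - 0.45)^2 + (cols - 0.55)^2) / 0.18))
  f / mean(f)
}

#' Simulate a donor/acceptor/FRET channel triplet
#'
#' Forward model per pixel: `FRET = efficiency * donor + alpha * donor +
#' beta * acceptor + noise`, with a camera floor added to all channels.
#' Donor-only or acceptor-only calibration stacks are produced by setting
#' `acceptor_present = FALSE` or `donor_present = FALSE`.
#'
#' @param shape `(rows, cols)` image size.
#' @param n_frames number of frames.
#' @param efficiency_map scalar or `(rows, cols)` matrix of true FRET
#'   efficiency in `[0, 1)`.
#' @param alpha donor-to-FRET bleed-through fraction in `[0, 1)`.
#' @param beta acceptor-to-FRET bleed-through fraction in `[0, 1)`.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param donor_present,acceptor_present logical; zero the corresponding
#'   fluorophore to emulate single-fluorophore calibration cells.
#' @param donor_level,acceptor_level peak fluorophore intensities; each
#'   channel varies smoothly across the cell so that regression inputs
#'   span a range of intensities.
#' @param background_level camera floor added everywhere.
#' @param pixel_size_um,frame_interval_s calibration of the output stack.
#' @return List with `stack` (channels `mTFP1`, `mVenus`, `FRET`) and
#'   `truth` (`true_alpha`, `true_beta`, `true_efficiency_map`, footprint).
#' @export
simulate_fret_triplet <- function(shape = c(128L, 128L), n_frames = 1L,
                                  efficiency_map = 0.2, alpha = 0.3072,
                                  beta = 0.05228, noise_sd = 0, seed = 1L,
                                  donor_present = TRUE,
                                  acceptor_present = TRUE,
                                  donor_level = 1000, acceptor_level = 1000,
                                  background_level = 20,
                                  pixel_size_um = 0.4,
                                  frame_interval_s = 180) {
  if (alpha < 0 || alpha >= 1 || beta < 0 || beta >= 1) {
    stop("alpha and beta must lie in [0, 1)")
  }
  h <- shape[1L]; w <- shape[2L]
  mask <- .cell_footprint(shape)
  if (is.matrix(efficiency_map)) {
    E <- efficiency_map
    if (!all(dim(E) == shape)) stop("efficiency_map shape mismatch")
  } else {
    E <- matrix(efficiency_map, h, w)
  }
  if (any(E[mask] < 0) || any(E[mask] >= 1)) {
    stop("efficiency must lie in [0, 1)")
  }
  set.seed(seed)
  # smooth deterministic intensity profile spanning ~[0.3, 1.7] x level
  dmap <- .distance_to_boundary(mask)
  prof <- matrix(0, h, w)
  if (max(dmap) > 0) prof[mask] <- 0.3 + 1.4 * dmap[mask] / max(dmap)
  donor0 <- if (donor_present) donor_level * prof else matrix(0, h, w)
  acceptor0 <- if (acceptor_present) acceptor_level * prof else matrix(0, h, w)
  # energy transfer requires both fluorophores in the cell
  if (!donor_present || !acceptor_present) E <- matrix(0, h, w)
  fret0 <- E * donor0 + alpha * donor0 + beta * acceptor0

  px <- array(0, dim = c(n_frames, 3L, h, w))
  for (t in seq_len(n_frames)) {
    add_noise <- function(m) {
      m <- m + background_level
      if (noise_sd > 0) m <- m + matrix(rnorm(h * w, sd = noise_sd), h, w)
      pmax(m, 0)
    }
    px[t, 1L, , ] <- add_noise(donor0)
    px[t, 2L, , ] <- add_noise(acceptor0)
    px[t, 3L, , ] <- add_noise(fret0)
  }
  stack <- channel_stack(px, c("mTFP1", "mVenus", "FRET"),
                         pixel_size_um, frame_interval_s)
  truth <- .new_ground_truth(
    true_alpha = alpha, true_beta = beta, true_efficiency_map = E,
    footprint = mask, background_level = background_level,
    noise_sd = noise_sd, seed = seed)
  list(stack = stack, truth = truth)
}

#' Simulate an EM-like actin meshwork image
#'
#' Random anti-aliased line segments (bright filaments on a dark
#' background) over a slowly varying background, with additive noise. The
#' planted porosity is the exact fraction of pixels not covered by any
#' filament; void component areas of the planted coverage mask are also
#' recorded.
#'
#' @param shape `(rows, cols)` image size.
#' @param n_filaments number of filament segments (>= 0).
#' @param filament_width_px filament width in px.
#' @param seed RNG seed.
#' @param filament_intensity peak filament brightness above background.
#' @param background_mean,background_bump mean level and amplitude of the
#'   smooth background.
#' @param noise_sd additive Gaussian noise SD.
#' @return List with `image` (matrix), `truth` (`true_porosity`,
#'   `coverage_mask`, `true_pore_areas_px2`).
#' @export
simulate_meshwork <- function(shape = c(192L, 192L), n_filaments = 60L,
                              filament_width_px = 3, seed = 1L,
                              filament_intensity = 150,
                              background_mean = 30, background_bump = 10,
                              noise_sd = 4) {
  if (any(shape <= 0)) stop("non-positive shape")
  if (n_filaments < 0) stop("n_filaments must be >= 0")
  set.seed(seed)
  h <- shape[1L]; w <- shape[2L]
  half <- filament_width_px / 2
  cover <- matrix(FALSE, h, w)
  intensity <- matrix(0, h, w)
  diag_len <- sqrt(h^2 + w^2)
  for (i in seq_len(n_filaments)) {
    # long filaments crossing the field: a random chord through a random
    # anchor point, as in micrographs of branched actin networks
    anchor <- c(runif(1, 1, h), runif(1, 1, w))
    theta <- runif(1, 0, pi)
    half_len <- runif(1, 0.35, 0.75) * diag_len
    p0 <- anchor - half_len * c(sin(theta), cos(theta))
    p1 <- anchor + half_len * c(sin(theta), cos(theta))
    r0 <- max(1L, floor(min(p0[1], p1[1]) - half - 1))
    r1 <- min(h, ceiling(max(p0[1], p1[1]) + half + 1))
    c0 <- max(1L, floor(min(p0[2], p1[2]) - half - 1))
    c1 <- min(w, ceiling(max(p0[2], p1[2]) + half + 1))
    rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
    cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
    # distance from each pixel centre to the segment
    vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
    len2 <- vx^2 + vy^2
    tt <- if (len2 > 0) pmin(1, pmax(0, ((rr - p0[1]) * vx + (cc - p0[2]) * vy) / len2)) else 0
    dist <- sqrt((rr - (p0[1] + tt * vx))^2 + (cc - (p0[2] + tt * vy))^2)
    cover[r0:r1, c0:c1] <- cover[r0:r1, c0:c1] | (dist <= half)
    aa <- pmin(1, pmax(0, half + 0.5 - dist))  # anti-aliased profile
    intensity[r0:r1, c0:c1] <- pmax(intensity[r0:r1, c0:c1], aa)
  }
  rows <- matrix(seq_len(h), h, w) / h
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  bg <- background_mean + background_bump * (rows - 0.5) * (cols - 0.5) * 4
  img <- bg + filament_intensity * intensity
  if (noise_sd > 0) img <- img + matrix(rnorm(h * w, sd = noise_sd), h, w)
  img <- pmax(img, 0)
  voids <- .label_components(!cover, 4L)
  areas <- as.numeric(table(voids[voids > 0]))
  truth <- .new_ground_truth(
    true_porosity = mean(!cover), coverage_mask = cover,
    true_pore_areas_px2 = areas, n_filaments = n_filaments,
    filament_width_px = filament_width_px, noise_sd = noise_sd, seed = seed)
  list(image = img, truth = truth)
}

#' Simulate a movie of a moving cell edge with a coupled near-edge signal
#'
#' The cell occupies the left part of the image; its edge advances or
#' retracts along the column axis per `phase_plan`. A reporter band just
#' inside the edge carries an intensity that is an affinely rescaled copy
#' of edge velocity shifted in time: positive `signal_lag_s` means the
#' signal *leads* the edge by that delay, so the cross-correlogram
#' (positive lag = signal leads) peaks at `+signal_lag_s`.
#'
#' @param n_frames number of frames.
#' @param phase_plan data frame with columns `phase`
#'   (`protrusion`/`stall`/`retraction`), `velocity_um_min`, `duration_s`;
#'   durations must sum to `n_frames * frame_interval_s`.
#' @param signal_lag_s lead of the near-edge signal over edge motion, s.
#' @param seed RNG seed.
#' @param shape `(rows, cols)` image size.
#' @param frame_interval_s,pixel_size_um calibration.
#' @param noise_sd additive Gaussian noise SD.
#' @param band_px width of the signal-carrying band inside the edge.
#' @param start_col_px initial edge column.
#' @param velocity_wobble_um_min SD of a smooth random fluctuation added
#'   to the planned velocity (Gaussian-smoothed white noise, sigma 2
#'   frames). A non-zero wobble gives the velocity series the temporal
#'   structure needed for a well-defined cross-correlation peak.
#' @return List with `stack` (single channel `ratio`), `truth`
#'   (`true_edge_position_um`, `true_velocity_um_min`, `true_phases`,
#'   `true_lag_s`, `signal_series`).
#' @export
simulate_edge_movie <- function(n_frames = 60L,
                                phase_plan = NULL,
                                signal_lag_s = 0, seed = 1L,
                                shape = c(48L, 160L),
                                frame_interval_s = 10,
                                pixel_size_um = 0.4,
                                noise_sd = 0, band_px = 4L,
                                start_col_px = 40,
                                velocity_wobble_um_min = 0) {
  if (is.null(phase_plan)) {
    phase_plan <- data.frame(
      phase = c("protrusion", "stall", "retraction"),
      velocity_um_min = c(2, 0, -1.5),
      duration_s = c(0.4, 0.3, 0.3) * n_frames * frame_interval_s)
  }
  total_s <- sum(phase_plan$duration_s)
  if (abs(total_s - n_frames * frame_interval_s) > 1e-6) {
    stop("phase_plan durations must sum to n_frames * frame_interval_s")
  }
  set.seed(seed)
  h <- shape[1L]; w <- shape[2L]
  n_per <- round(phase_plan$duration_s / frame_interval_s)
  # fix rounding so phase frame counts sum to n_frames
  while (sum(n_per) > n_frames) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
  while (sum(n_per) < n_frames) n_per[which.max(n_per)] <- n_per[which.max(n_per)] + 1L
  v <- rep(phase_plan$velocity_um_min, times = n_per)       # um/min
  if (velocity_wobble_um_min > 0) {
    wob <- .gauss_smooth1d(rnorm(n_frames), 2)
    v <- v + velocity_wobble_um_min * wob / sd(wob)
  }
  phases <- rep(as.character(phase_plan$phase), times = n_per)
  dt_min <- frame_interval_s / 60
  pos_px <- start_col_px +
    cumsum(c(0, v[-n_frames])) * dt_min / pixel_size_um
  if (any(pos_px < band_px + 2) || any(pos_px > w - 2)) {
    stop("edge trajectory leaves the field of view; enlarge shape")
  }
  # signal leads edge by lag: s(t) = v(t + lag_frames)
  lag_f <- round(signal_lag_s / frame_interval_s)
  idx <- pmin(n_frames, pmax(1L, seq_len(n_frames) + lag_f))
  s <- v[idx]
  rng <- range(v)
  s_unit <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else rep(0.5, n_frames)
  band_int <- 120 + 60 * s_unit

  cell_int <- 100; bg_int <- 10
  px <- array(0, dim = c(n_frames, 1L, h, w))
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (t in seq_len(n_frames)) {
    img <- matrix(bg_int, h, w)
    inside <- cols <= pos_px[t]
    img[inside] <- cell_int
    # signal band sits just inside a 1 px rim of constant cell intensity,
    # so the outermost edge step has time-invariant contrast
    band <- cols > pos_px[t] - 1 - band_px & cols <= pos_px[t] - 1
    img[band] <- band_int[t]
    # partial-volume edge pixel: the pixel straddling the edge carries a
    # coverage-weighted intensity, as a finite-resolution detector would
    frac <- pos_px[t] - floor(pos_px[t])
    ec <- floor(pos_px[t]) + 1L
    if (frac > 0 && ec <= w) {
      img[, ec] <- bg_int + frac * (cell_int - bg_int)
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, sd = noise_sd), h, w)
    px[t, 1L, , ] <- pmax(img, 0)
  }
  stack <- channel_stack(px, "ratio", pixel_size_um, frame_interval_s)
  truth <- .new_ground_truth(
    true_edge_position_um = pos_px * pixel_size_um,
    true_velocity_um_min = v, true_phases = phases,
    true_lag_s = signal_lag_s, signal_series = band_int,
    band_px = band_px, seed = seed)
  list(stack = stack, truth = truth)
}

#' Simulate nucleus detections from correlated random walks
#'
#' Cells take constant-length steps (`speed_um_min * frame_interval`);
#' heading changes between frames by a uniform turn scaled by
#' `1 - persistence`, so `persistence = 1` gives straight lines and
#' `persistence = 0` an uncorrelated random walk. Detections may be
#' dropped at random (never in the first or last frame of a cell) to
#' exercise gap closing.
#'
#' @param n_cells,n_frames numbers of cells and frames (>= 1).
#' @param speed_um_min step speed, um/min.
#' @param persistence directional persistence in `[0, 1]`.
#' @param frame_interval_s frame interval, s.
#' @param seed RNG seed.
#' @param dropout per-detection probability of a missed detection.
#' @param spacing_um grid spacing between cell start positions.
#' @return List with `detections` (data frame `frame`, `x_um`, `y_um`,
#'   `quality`, `true_track`) and `truth` (`true_tracks` data frame of all
#'   positions, plus the generating parameters).
#' @export
simulate_tracks <- function(n_cells = 5L, n_frames = 20L, speed_um_min = 1,
                            persistence = 0.5, frame_interval_s = 720,
                            seed = 1L, dropout = 0, spacing_um = 250) {
  if (n_cells < 1 || n_frames < 1) stop("n_cells and n_frames must be >= 1")
  if (persistence < 0 || persistence > 1) stop("persistence outside [0, 1]")
  set.seed(seed)
  dt_min <- frame_interval_s / 60
  step <- speed_um_min * dt_min
  n_col <- ceiling(sqrt(n_cells))
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    x0 <- ((i - 1) %% n_col) * spacing_um
    y0 <- ((i - 1) %/% n_col) * spacing_um
    theta <- runif(1, -pi, pi)
    x <- numeric(n_frames); y <- numeric(n_frames)
    x[1] <- x0; y[1] <- y0
    for (t in seq_len(n_frames - 1L)) {
      theta <- theta + (1 - persistence) * runif(1, -pi, pi)
      x[t + 1L] <- x[t] + step * cos(theta)
      y[t + 1L] <- y[t] + step * sin(theta)
    }
    out[[i]] <- data.frame(frame = seq_len(n_frames), x_um = x, y_um = y,
                           quality = 1, true_track = i)
  }
  truth_tracks <- do.call(rbind, out)
  det <- truth_tracks
  if (dropout > 0 && n_frames > 2) {
    droppable <- det$frame > 1 & det$frame < n_frames
    keep <- !(droppable & runif(nrow(det)) < dropout)
    det <- det[keep, , drop = FALSE]
  }
  det <- det[order(det$frame, det$true_track), , drop = FALSE]
  rownames(det) <- NULL
  truth <- .new_ground_truth(
    true_tracks = truth_tracks, speed_um_min = speed_um_min,
    persistence = persistence, frame_interval_s = frame_interval_s,
    dropout = dropout, seed = seed)
  list(detections = det, truth = truth)
}

#' Simulate a focal-adhesion area table
#'
#' Draws object areas uniformly within the nascent `[0.05, 0.20)`, mature
#' `[0.20, 1.75]` and fibrillar `(1.75, 5]` um^2 bins.
#'
#' @param counts_per_class integer vector `(nascent, mature, fibrillar)`.
#' @param seed RNG seed.
#' @return Data frame with `area_um2` and `true_class`.
#' @export
simulate_adhesion_table <- function(counts_per_class = c(5L, 5L, 5L),
                                    seed = 1L) {
  if (any(counts_per_class < 0)) stop("counts must be >= 0")
  set.seed(seed)
  lo <- c(0.05, 0.20, 1.76)
  hi <- c(0.199, 1.75, 5)
  cls <- c("nascent", "mature", "fibrillar")
  out <- do.call(rbind, lapply(1:3, function(k) {
    n <- counts_per_class[k]
    if (n == 0) return(NULL)
    data.frame(area_um2 = runif(n, lo[k], hi[k]), true_class = cls[k])
  }))
  if (is.null(out)) out <- data.frame(area_um2 = numeric(0),
                                      true_class = character(0))
  rownames(out) <- NULL
  out
}
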