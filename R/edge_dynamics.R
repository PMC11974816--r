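# Kymograph construction, cell-edge tracing, spreading/protrusion speed
# estimation and protrusion-phase classification.
#
# Sign convention: the sampling line runs from the cell interior (start)
# to the exterior (end); outward edge motion is positive.

#' Build a kymograph along a line
#'
#' Samples intensity by bilinear interpolation along the line from `p0`
#' (cell interior) to `p1` (exterior), averaged across `width_px` parallel
#' lines offset along the line normal, for every frame.
#'
#' @param stack a [channel_stack()].
#' @param channel channel name or index.
#' @param p0,p1 line endpoints `(row, col)` in pixel coordinates; `p0` on
#'   the cell side.
#' @param width_px odd number of parallel lines averaged (default 3).
#' @return Object of class `Kymograph`: `values` (space x time matrix,
#'   row 1 at `p0`), `space_step_um`, `time_step_s`, `line` geometry.
#' @export
build_kymograph <- function(stack, channel, p0, p1, width_px = 3L) {
  stopifnot(inherits(stack, "ChannelStack"))
  if (width_px %% 2L != 1L || width_px < 1L) stop("width_px must be odd")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  len_px <- sqrt(sum((p1 - p0)^2))
  if (len_px <= 0) stop("degenerate line")
  d <- dim(stack$pixels)
  n_s <- floor(len_px) + 1L
  tvec <- (p1 - p0) / len_px                      # unit tangent
  nvec <- c(-tvec[2L], tvec[1L])                  # unit normal
  ss <- seq(0, len_px, length.out = n_s)
  offs <- seq_len(width_px) - (width_px + 1L) / 2
  base_r <- p0[1L] + ss * tvec[1L]
  base_c <- p0[2L] + ss * tvec[2L]
  if (all(base_r < 1 | base_r > d[3L]) || all(base_c < 1 | base_c > d[4L])) {
    stop("line lies outside the image")
  }
  vals <- matrix(0, n_s, d[1L])
  for (t in seq_len(d[1L])) {
    img <- get_frame(stack, t, channel)
    acc <- numeric(n_s)
    for (o in offs) {
      acc <- acc + .bilinear(img, base_r + o * nvec[1L],
                             base_c + o * nvec[2L])
    }
    vals[, t] <- acc / width_px
  }
  structure(list(values = vals,
                 space_step_um = (len_px / (n_s - 1L)) * stack$pixel_size_um,
                 time_step_s = stack$frame_interval_s,
                 line = list(p0 = p0, p1 = p1, width_px = width_px)),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d px x %d frames (%.3g um/px, %.3g s/frame)\n",
              nrow(x$values), ncol(x$values), x$space_step_um, x$time_step_s))
  invisible(x)
}

#' Trace the cell edge through a kymograph
#'
#' Per frame, the edge is the outermost crossing of the per-kymograph Otsu
#' threshold (foreground above background along the line), refined to
#' sub-pixel position by linear interpolation. Frames without a crossing
#' are linearly interpolated from neighbours and flagged.
#'
#' @param kym a [build_kymograph()] result.
#' @return Object of class `EdgeTrace`: data frame `frame`, `time_s`,
#'   `position_um`, `velocity_um_min` (centred finite difference),
#'   `interpolated`; attributes carry the kymograph calibration.
#' @export
trace_edge <- function(kym) {
  v <- kym$values
  n_s <- nrow(v); n_t <- ncol(v)
  thr <- .otsu_threshold(v)
  pos <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    col <- v[, t]
    above <- col >= thr
    if (!above[1L] || all(above)) {
      # no interior foreground or no crossing
      cross <- integer(0)
    } else {
      cross <- which(above[-n_s] & !above[-1L])  # outermost above->below
    }
    if (length(cross) > 0L) {
      i <- max(cross)
      frac <- (col[i] - thr) / (col[i] - col[i + 1L])
      pos[t] <- (i - 1L) + frac
    }
  }
  missing <- is.na(pos)
  if (mean(missing) > 0.5) stop("edge not detectable in >50% of frames")
  if (any(missing)) {
    pos <- approx(which(!missing), pos[!missing], xout = seq_len(n_t),
                  rule = 2)$y
  }
  pos_um <- pos * kym$space_step_um
  dt_min <- kym$time_step_s / 60
  vel <- rep(NA_real_, n_t)
  if (n_t >= 2L) {
    vel[1L] <- (pos_um[2L] - pos_um[1L]) / dt_min
    vel[n_t] <- (pos_um[n_t] - pos_um[n_t - 1L]) / dt_min
    if (n_t >= 3L) {
      vel[2:(n_t - 1L)] <- (pos_um[3:n_t] - pos_um[1:(n_t - 2L)]) / (2 * dt_min)
    }
  }
  structure(data.frame(frame = seq_len(n_t),
                       time_s = (seq_len(n_t) - 1L) * kym$time_step_s,
                       position_um = pos_um, velocity_um_min = vel,
                       interpolated = missing),
            class = c("EdgeTrace", "data.frame"),
            time_step_s = kym$time_step_s)
}

# Build an EdgeTrace directly from position data (useful for planted
# trajectories and tests).
#' Construct an edge trace from positions
#'
#' @param position_um edge position per frame, um.
#' @param time_step_s frame interval, s.
#' @return An `EdgeTrace` as from [trace_edge()].
#' @export
edge_trace <- function(position_um, time_step_s) {
  n_t <- length(position_um)
  dt_min <- time_step_s / 60
  vel <- rep(NA_real_, n_t)
  if (n_t >= 2L) {
    vel[1L] <- (position_um[2L] - position_um[1L]) / dt_min
    vel[n_t] <- (position_um[n_t] - position_um[n_t - 1L]) / dt_min
    if (n_t >= 3L) {
      vel[2:(n_t - 1L)] <-
        (position_um[3:n_t] - position_um[1:(n_t - 2L)]) / (2 * dt_min)
    }
  }
  structure(data.frame(frame = seq_len(n_t),
                       time_s = (seq_len(n_t) - 1L) * time_step_s,
                       position_um = position_um, velocity_um_min = vel,
                       interpolated = FALSE),
            class = c("EdgeTrace", "data.frame"),
            time_step_s = time_step_s)
}

#' Average spreading speed from an edge trace
#'
#' The fast spreading phase is operationalised as the contiguous window
#' (minimum length `min_frac` of the trace) that maximises mean outward
#' velocity; the reported speed is the least-squares slope of position
#' over time within that window.
#'
#' @param trace an `EdgeTrace` spanning >= 10 frames.
#' @param min_frac minimum window length as a fraction of the trace.
#' @return Speed in um/min (negative if the best window retracts).
#' @export
spreading_speed <- function(trace, min_frac = 0.2) {
  n <- nrow(trace)
  if (n < 10L) stop("trace too short (< 10 frames)")
  pos <- trace$position_um
  t_min <- trace$time_s / 60
  min_len <- max(2L, ceiling(min_frac * n))
  # mean velocity over window [i, j] ~ (pos[j] - pos[i]) / (t[j] - t[i])
  best <- -Inf; bi <- 1L; bj <- n
  for (i in seq_len(n - min_len + 1L)) {
    js <- (i + min_len - 1L):n
    rates <- (pos[js] - pos[i]) / (t_min[js] - t_min[i])
    k <- which.max(rates)
    if (rates[k] > best) { best <- rates[k]; bi <- i; bj <- js[k] }
  }
  win <- bi:bj
  unname(coef(lm(pos[win] ~ t_min[win]))[2L])
}

#' Classify protrusion/stall/retraction phases
#'
#' Frames with velocity above `+v_stall` are protrusion, below `-v_stall`
#' retraction, otherwise stall. Runs shorter than `min_run` frames are
#' merged into the longer adjacent run.
#'
#' @param trace an `EdgeTrace`.
#' @param v_stall stall threshold, um/min (default 0.5).
#' @param min_run minimum run length in frames (default 3).
#' @return Character vector of phases, one per frame.
#' @export
classify_phases <- function(trace, v_stall = 0.5, min_run = 3L) {
  v <- trace$velocity_um_min
  ph <- ifelse(v > v_stall, "protrusion",
               ifelse(v < -v_stall, "retraction", "stall"))
  ph[is.na(v)] <- "stall"
  if (min_run > 1L) {
    repeat {
      r <- rle(ph)
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < min_run)
      if (length(short) == 0L) break
      k <- short[which.min(r$lengths[short])]
      left_len <- if (k > 1L) r$lengths[k - 1L] else -1L
      right_len <- if (k < length(r$lengths)) r$lengths[k + 1L] else -1L
      r$values[k] <- if (left_len >= right_len) {
        r$values[k - 1L]
      } else {
        r$values[k + 1L]
      }
      ph <- inverse.rle(r)
    }
  }
  ph
}

#' Mean lamellipodial protrusion speed
#'
#' Protrusion events are maximal runs classified as protrusion with total
#' outward displacement of at least `min_event_um`; the `n_events`
#' largest-displacement events are kept and the mean of their per-event
#' regression slopes of position on time is returned.
#'
#' @param trace an `EdgeTrace`.
#' @param n_events number of events averaged (default 5).
#' @param v_stall,min_run phase-classification parameters.
#' @param min_event_um minimum event displacement, um.
#' @return Speed in um/min.
#' @export
protrusion_speed <- function(trace, n_events = 5L, v_stall = 0.5,
                             min_run = 3L, min_event_um = 0.2) {
  ph <- classify_phases(trace, v_stall, min_run)
  r <- rle(ph)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values == "protrusion")
  if (length(ev) > 0L) {
    disp <- trace$position_um[ends[ev]] - trace$position_um[starts[ev]]
    ok <- disp >= min_event_um & r$lengths[ev] >= 2L
    ev <- ev[ok]; disp <- disp[ok]
  }
  if (length(ev) < n_events) {
    stop(sprintf("only %d protrusion event(s) detected; %d required",
                 length(ev), n_events))
  }
  sel <- ev[order(disp, decreasing = TRUE)][seq_len(n_events)]
  slopes <- vapply(sel, function(k) {
    win <- starts[k]:ends[k]
    unname(coef(lm(trace$position_um[win] ~ I(trace$time_s[win] / 60)))[2L])
  }, numeric(1))
  mean(slopes)
}
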