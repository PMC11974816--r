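# Nucleus detection (LoG), LAP-style track linking with gap closing,
# track filtering and migration metrics.

#' Laplacian-of-Gaussian blob detection
#'
#' Detects bright blobs at the scale `sigma = diameter / (2*sqrt(2))`
#' (in px after calibration). The response is the scale-normalised
#' negative Laplacian of the Gaussian-smoothed image; per-image quality
#' is the response normalised to the image maximum, so the threshold is
#' transferable across intensity scales. Detections are local maxima
#' with quality at or above the threshold, refined to sub-pixel position
#' by a quadratic fit.
#'
#' @param image 2-D intensity matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param diameter_um estimated object diameter (default 25).
#' @param quality_threshold minimum normalised response (default 0.08).
#' @param frame frame index stored on the detections.
#' @return Data frame `frame`, `x_um`, `y_um`, `quality` (x along
#'   columns, y along rows, origin at the first pixel centre).
#' @export
detect_blobs_log <- function(image, pixel_size_um, diameter_um = 25,
                             quality_threshold = 0.08, frame = 1L) {
  sigma_px <- diameter_um / (2 * sqrt(2)) / pixel_size_um
  if (diameter_um / pixel_size_um < 2) stop("diameter smaller than 2 px")
  sm <- .gauss_blur2d(image, sigma_px)
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  lap <- as.matrix(EBImage::filter2(EBImage::Image(sm), lap_kernel))
  resp <- -sigma_px^2 * lap
  mx <- max(resp)
  if (mx <= 0) {
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), quality = numeric(0)))
  }
  q <- resp / mx
  h <- nrow(resp); w <- ncol(resp)
  is_max <- q >= quality_threshold
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    is_max <- is_max & resp >= .shift_int(resp, d[1L], d[2L], fill = -Inf)
  }
  idx <- which(is_max)
  if (length(idx) == 0L) {
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), quality = numeric(0)))
  }
  pr <- ((idx - 1L) %% h) + 1L
  pc <- ((idx - 1L) %/% h) + 1L
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    ifelse(abs(den) < .Machine$double.eps, 0,
           pmax(-0.5, pmin(0.5, 0.5 * (vm - vp) / den)))
  }
  dr <- dc <- numeric(length(idx))
  inner <- pr > 1L & pr < h & pc > 1L & pc < w
  if (any(inner)) {
    ii <- which(inner)
    dr[ii] <- refine(resp[cbind(pr[ii] - 1L, pc[ii])],
                     resp[cbind(pr[ii], pc[ii])],
                     resp[cbind(pr[ii] + 1L, pc[ii])])
    dc[ii] <- refine(resp[cbind(pr[ii], pc[ii] - 1L)],
                     resp[cbind(pr[ii], pc[ii])],
                     resp[cbind(pr[ii], pc[ii] + 1L)])
  }
  data.frame(frame = frame,
             x_um = (pc - 1 + dc) * pixel_size_um,
             y_um = (pr - 1 + dr) * pixel_size_um,
             quality = q[idx])
}

# Solve one LAP linking step between two point sets (Jaqaman-style
# augmented matrix with birth/death alternatives). Returns an integer
# vector: for each row point, the matched column point or NA.
.lap_link <- function(xy1, xy2, max_dist) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  big <- 1e9
  d2 <- outer(xy1[, 1L], xy2[, 1L], "-")^2 +
    outer(xy1[, 2L], xy2[, 2L], "-")^2
  link <- d2
  link[sqrt(d2) > max_dist] <- big
  alt <- max_dist^2
  n <- n1 + n2
  cost <- matrix(big, n, n)
  cost[seq_len(n1), seq_len(n2)] <- link
  for (i in seq_len(n1)) cost[i, n2 + i] <- alt
  for (j in seq_len(n2)) cost[n1 + j, j] <- alt
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  sol <- .solve_assignment(cost)
  out <- rep(NA_integer_, n1)
  hit <- sol[seq_len(n1)] <= n2
  out[hit] <- sol[seq_len(n1)][hit]
  out
}

#' Link detections into tracks (LAP with gap closing)
#'
#' Frame-to-frame assignment minimising total squared displacement, with
#' a non-link alternative at `max_link_um` (optimal bipartite
#' assignment), followed by track-segment gap closing that joins
#' segment ends to later segment starts within `gap_close_um` and at
#' most `max_frame_gap` frames, again by optimal assignment.
#'
#' @param detections data frame with `frame`, `x_um`, `y_um` (extra
#'   columns are carried through).
#' @param max_link_um frame-to-frame linking radius (default 50).
#' @param gap_close_um gap-closing radius (default 50).
#' @param max_frame_gap largest bridgeable frame difference (default 3).
#' @return A `TrackTable`: data frame `track_id`, `frame`, `x_um`,
#'   `y_um`, ... sorted by track then frame. Empty input gives an empty
#'   table.
#' @export
link_tracks <- function(detections, max_link_um = 50, gap_close_um = 50,
                        max_frame_gap = 3L) {
  det <- as.data.frame(detections)
  if (nrow(det) == 0L) {
    return(structure(cbind(data.frame(track_id = integer(0)), det),
                     class = c("TrackTable", "data.frame")))
  }
  det <- det[order(det$frame), , drop = FALSE]
  det$.row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  seg_of <- rep(NA_integer_, nrow(det))
  n_seg <- 0L
  by_frame <- split(det, det$frame)
  # first frame: every detection opens a segment
  first <- by_frame[[as.character(frames[1L])]]
  seg_of[first$.row] <- seq_len(nrow(first))
  n_seg <- nrow(first)
  if (length(frames) > 1L) {
    for (fi in seq_len(length(frames) - 1L)) {
      f1 <- frames[fi]; f2 <- frames[fi + 1L]
      cur <- by_frame[[as.character(f2)]]
      if (f2 - f1 == 1L) {
        prev <- by_frame[[as.character(f1)]]
        m <- .lap_link(cbind(prev$x_um, prev$y_um),
                       cbind(cur$x_um, cur$y_um), max_link_um)
        for (i in seq_along(m)) {
          if (!is.na(m[i])) {
            seg_of[cur$.row[m[i]]] <- seg_of[prev$.row[i]]
          }
        }
      }
      new <- is.na(seg_of[cur$.row])
      if (any(new)) {
        seg_of[cur$.row[new]] <- n_seg + seq_len(sum(new))
        n_seg <- n_seg + sum(new)
      }
    }
  }
  det$segment <- seg_of
  # gap closing between segment ends and later segment starts
  seg_list <- split(det, det$segment)
  ends <- t(vapply(seg_list, function(s) {
    s <- s[order(s$frame), ]
    c(s$frame[nrow(s)], s$x_um[nrow(s)], s$y_um[nrow(s)])
  }, numeric(3)))
  starts <- t(vapply(seg_list, function(s) {
    s <- s[order(s$frame), ]
    c(s$frame[1L], s$x_um[1L], s$y_um[1L])
  }, numeric(3)))
  ns <- length(seg_list)
  if (ns > 1L && max_frame_gap >= 2L) {
    big <- 1e9
    cost <- matrix(big, 2L * ns, 2L * ns)
    any_pair <- FALSE
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (i == j) next
      df <- starts[j, 1L] - ends[i, 1L]
      if (df >= 2 && df <= max_frame_gap) {
        d <- sqrt((ends[i, 2L] - starts[j, 2L])^2 +
                    (ends[i, 3L] - starts[j, 3L])^2)
        if (d <= gap_close_um) {
          cost[i, j] <- d^2
          any_pair <- TRUE
        }
      }
    }
    if (any_pair) {
      alt <- gap_close_um^2
      for (i in seq_len(ns)) cost[i, ns + i] <- alt
      for (j in seq_len(ns)) cost[ns + j, j] <- alt
      cost[ns + seq_len(ns), ns + seq_len(ns)] <- 0
      sol <- .solve_assignment(cost)
      succ <- rep(NA_integer_, ns)
      for (i in seq_len(ns)) if (sol[i] <= ns) succ[i] <- sol[i]
      # merge chains end -> start
      has_pred <- rep(FALSE, ns)
      has_pred[succ[!is.na(succ)]] <- TRUE
      track_of_seg <- rep(NA_integer_, ns)
      tid <- 0L
      for (i in which(!has_pred)) {
        tid <- tid + 1L
        k <- i
        while (!is.na(k)) {
          track_of_seg[k] <- tid
          k <- succ[k]
        }
      }
      det$track_id <- track_of_seg[det$segment]
    } else {
      det$track_id <- det$segment
    }
  } else {
    det$track_id <- det$segment
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  det$.row <- NULL
  det$segment <- NULL
  det <- det[, c("track_id", setdiff(names(det), "track_id")), drop = FALSE]
  rownames(det) <- NULL
  structure(det, class = c("TrackTable", "data.frame"))
}

#' Per-track migration metrics
#'
#' Path length is the sum of consecutive Euclidean steps; displacement
#' the straight-line distance from first to last point; speed is
#' path / duration and the directionality index (DI) is
#' displacement / path (0 for zero path).
#'
#' @param track data frame of one track's rows (`frame`, `x_um`, `y_um`,
#'   optional `z_um`), >= 2 points.
#' @param frame_interval_s seconds per frame.
#' @return List `path_um`, `displacement_um`, `duration_min`,
#'   `speed_um_min`, `di`.
#' @export
migration_metrics <- function(track, frame_interval_s) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L) stop("track needs >= 2 points")
  cols <- intersect(c("x_um", "y_um", "z_um"), names(track))
  xyz <- as.matrix(track[, cols, drop = FALSE])
  steps <- sqrt(rowSums(diff(xyz)^2))
  path <- sum(steps)
  disp <- sqrt(sum((xyz[n, ] - xyz[1L, ])^2))
  dur_min <- (track$frame[n] - track$frame[1L]) * frame_interval_s / 60
  list(path_um = path, displacement_um = disp, duration_min = dur_min,
       speed_um_min = path / dur_min,
       di = if (path > 0) disp / path else 0)
}

#' Straight-line displacement speed of a track
#'
#' Net displacement divided by track duration, reported in um/hr (the
#' convention for slow 3-D migration).
#'
#' @inheritParams migration_metrics
#' @return Speed in um/hr.
#' @export
displacement_speed <- function(track, frame_interval_s) {
  m <- migration_metrics(track, frame_interval_s)
  if (m$duration_min <= 0) stop("zero track duration")
  m$displacement_um / (m$duration_min / 60)
}

#' Metrics for every track in a table
#'
#' @param tracks a `TrackTable` from [link_tracks()].
#' @param frame_interval_s seconds per frame.
#' @return Data frame, one row per track: `track_id`, `n_points`,
#'   `duration_min`, `path_um`, `displacement_um`, `speed_um_min`, `di`.
#' @export
track_metrics <- function(tracks, frame_interval_s) {
  out <- lapply(split(as.data.frame(tracks), tracks$track_id), function(s) {
    if (nrow(s) < 2L) {
      return(data.frame(track_id = s$track_id[1L], n_points = nrow(s),
                        duration_min = 0, path_um = 0, displacement_um = 0,
                        speed_um_min = NA_real_, di = NA_real_))
    }
    m <- migration_metrics(s, frame_interval_s)
    data.frame(track_id = s$track_id[1L], n_points = nrow(s),
               duration_min = m$duration_min, path_um = m$path_um,
               displacement_um = m$displacement_um,
               speed_um_min = m$speed_um_min, di = m$di)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter tracks by duration and span
#'
#' Keeps tracks lasting at least `min_duration_min` and spanning at
#' least `min_span_um`. Span is path length by default (`span =
#' "path"`); `span = "displacement"` uses net displacement instead.
#'
#' @param tracks a `TrackTable`.
#' @param frame_interval_s seconds per frame.
#' @param min_duration_min minimum duration (default 60).
#' @param min_span_um minimum span (default 18).
#' @param span `"path"` or `"displacement"`.
#' @return The filtered `TrackTable`; attribute `n_removed` counts
#'   discarded tracks.
#' @export
filter_tracks <- function(tracks, frame_interval_s, min_duration_min = 60,
                          min_span_um = 18, span = c("path", "displacement")) {
  span <- match.arg(span)
  if (nrow(tracks) == 0L) return(tracks)
  m <- track_metrics(tracks, frame_interval_s)
  sp <- if (span == "path") m$path_um else m$displacement_um
  keep_ids <- m$track_id[m$duration_min >= min_duration_min &
                           sp >= min_span_um & m$n_points >= 2L]
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(m) - length(keep_ids)
  class(out) <- c("TrackTable", "data.frame")
  out
}

#' Read or write TrackMate-style track CSV
#'
#' Columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y` (and
#' `POSITION_Z` when present) are mapped to the package's `track_id`,
#' `frame`, `x_um`, `y_um`, `z_um`.
#'
#' @param path CSV file path.
#' @return A `TrackTable`.
#' @export
read_trackmate_csv <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(raw))) {
    stop("missing TrackMate columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  out <- data.frame(track_id = raw$TRACK_ID, frame = raw$FRAME,
                    x_um = raw$POSITION_X, y_um = raw$POSITION_Y)
  if ("POSITION_Z" %in% names(raw)) out$z_um <- raw$POSITION_Z
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("TrackTable", "data.frame"))
}

#' @rdname read_trackmate_csv
#' @param tracks a `TrackTable` to write.
#' @export
write_trackmate_csv <- function(tracks, path) {
  out <- data.frame(TRACK_ID = tracks$track_id, FRAME = tracks$frame,
                    POSITION_X = tracks$x_um, POSITION_Y = tracks$y_um)
  if ("z_um" %in% names(tracks)) out$POSITION_Z <- tracks$z_um
  write_table(out, path)
}
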