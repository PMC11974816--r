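# Lamellipodial intensity morphometrics, marker-enriched perimeter
# fraction, and focal-adhesion area classification.

#' Maximum-intensity projection with background subtraction
#'
#' Per-pixel maximum over z followed by [subtract_background()].
#'
#' @param zstack 3-D array `(z, row, col)` (a single 2-D matrix is
#'   accepted as one slice).
#' @return List with `image` and `background_level`.
#' @export
project_and_clean <- function(zstack) {
  if (is.matrix(zstack)) zstack <- array(zstack, c(1L, dim(zstack)))
  d <- dim(zstack)
  if (length(d) != 3L || d[1L] < 1L) stop("zstack must have >= 1 slice")
  mip <- apply(zstack, c(2L, 3L), max)
  subtract_background(mip)
}

#' Mean intensity inside a polygonal ROI
#'
#' Pixels whose centres fall inside the polygon (even-odd rule) are
#' averaged.
#'
#' @param image 2-D intensity matrix.
#' @param roi_polygon n x 2 matrix of (row, col) vertices, n >= 3,
#'   implicitly closed.
#' @param roi_id identifier stored on the result.
#' @param channel channel label stored on the result.
#' @return Data frame (one row) with `roi_id`, `channel`,
#'   `mean_intensity`, `n_pixels`, and `normalized_intensity` (`NA` until
#'   [normalize_to_control()]).
#' @export
roi_mean <- function(image, roi_polygon, roi_id = 1L, channel = NA_character_) {
  poly <- as.matrix(roi_polygon)
  if (nrow(poly) < 3L) stop("polygon needs >= 3 vertices")
  if (abs(pracma::polyarea(poly[, 1L], poly[, 2L])) <= 0) {
    stop("degenerate polygon with zero area")
  }
  h <- nrow(image); w <- ncol(image)
  rows <- as.numeric(matrix(seq_len(h), h, w))
  cols <- as.numeric(matrix(seq_len(w), h, w, byrow = TRUE))
  inside <- pracma::inpolygon(rows, cols, poly[, 1L], poly[, 2L],
                              boundary = TRUE)
  if (!any(inside)) stop("polygon contains no pixel centres")
  data.frame(roi_id = roi_id, channel = channel,
             mean_intensity = mean(image[inside]),
             n_pixels = sum(inside),
             normalized_intensity = NA_real_)
}

#' Normalise ROI measurements to a control group
#'
#' Each measurement's `normalized_intensity` becomes its mean intensity
#' divided by the mean of the control measurements' means, so the control
#' group averages exactly 1.
#'
#' @param measurements data frame as from [roi_mean()] (rows stackable
#'   with `rbind`).
#' @param control_ids values of `roi_id` forming the control group.
#' @return The data frame with `normalized_intensity` filled in.
#' @export
normalize_to_control <- function(measurements, control_ids) {
  ctrl <- measurements$roi_id %in% control_ids
  if (!any(ctrl)) stop("empty control set")
  m0 <- mean(measurements$mean_intensity[ctrl])
  if (m0 <= 0) stop("control mean must be > 0")
  measurements$normalized_intensity <- measurements$mean_intensity / m0
  measurements
}

# Ordered boundary chain of a mask (Moore-neighbour tracing of the
# largest component's outer boundary). Returns an n x 2 (row, col) matrix.
.boundary_chain <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  start <- which(pad, arr.ind = TRUE)
  start <- start[order(start[, 2L], start[, 1L]), , drop = FALSE][1L, ]
  # Moore neighbourhood, clockwise starting West
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  chain <- matrix(start, 1L, 2L)
  cur <- start
  dir <- 1L  # came from the West
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir - 1L + k) %% 8L) + 1L
      cand <- cur + nb[d, ]
      if (pad[cand[1L], cand[2L]]) {
        chain <- rbind(chain, cand)
        # next search starts from the direction opposite the step back
        dir <- ((d - 1L + 6L) %% 8L) + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && nrow(chain) > 2L) break
  }
  if (nrow(chain) > 1L) chain <- chain[-nrow(chain), , drop = FALSE]
  chain - 1L  # un-pad
}

#' Fraction of the cell perimeter enriched for a marker
#'
#' The enrichment threshold is the whole-cell mean plus `k_sd` standard
#' deviations of the in-mask marker intensity. The mask boundary is
#' traced as an ordered pixel chain; a boundary point counts as enriched
#' when the mean marker intensity over the in-mask pixels within
#' `band_px` of it exceeds the threshold. The enriched chain length over
#' the total chain length is returned.
#'
#' @param marker_image 2-D marker intensity matrix.
#' @param cell_mask a [binary_mask()] of the cell.
#' @param k_sd threshold multiplier (default 1.5).
#' @param band_px inward band depth in px (default 5).
#' @return Fraction in `[0, 1]`.
#' @export
enriched_perimeter_fraction <- function(marker_image, cell_mask, k_sd = 1.5,
                                        band_px = 5L) {
  mask <- cell_mask$pixels
  if (!any(mask)) stop("empty mask")
  vals <- marker_image[mask]
  thr <- mean(vals) + k_sd * sd(vals)
  chain <- .boundary_chain(mask)
  if (nrow(chain) == 0L) stop("empty boundary")
  h <- nrow(mask); w <- ncol(mask)
  enriched <- logical(nrow(chain))
  for (i in seq_len(nrow(chain))) {
    r0 <- max(1L, chain[i, 1L] - band_px); r1 <- min(h, chain[i, 1L] + band_px)
    c0 <- max(1L, chain[i, 2L] - band_px); c1 <- min(w, chain[i, 2L] + band_px)
    rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
    cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
    near <- (rr - chain[i, 1L])^2 + (cc - chain[i, 2L])^2 <= band_px^2
    sub_mask <- mask[r0:r1, c0:c1] & near
    if (any(sub_mask)) {
      enriched[i] <- mean(marker_image[r0:r1, c0:c1][sub_mask]) > thr
    }
  }
  mean(enriched)
}

#' Classify focal adhesions by area
#'
#' Nascent adhesions occupy `[0.05, 0.20)` um^2, mature `[0.20, 1.75]`
#' and fibrillar `(1.75, Inf)` (half-open convention at the shared
#' edges). Areas below 0.05 um^2 are dropped and counted.
#'
#' @param areas numeric vector of object areas, um^2 (>= 0).
#' @return Object of class `AdhesionTable`: data frame `area_um2`,
#'   `class`; attributes `fractions` (named, over classified objects) and
#'   `n_dropped`.
#' @export
classify_adhesions <- function(areas) {
  if (any(areas < 0)) stop("areas must be >= 0")
  dropped <- areas < 0.05
  a <- areas[!dropped]
  cls <- ifelse(a < 0.20, "nascent",
                ifelse(a <= 1.75, "mature", "fibrillar"))
  tab <- data.frame(area_um2 = a,
                    class = factor(cls, levels = c("nascent", "mature",
                                                   "fibrillar")))
  fr <- if (nrow(tab)) {
    prop.table(table(tab$class))
  } else {
    table(factor(character(0), levels = levels(tab$class)))
  }
  structure(tab, class = c("AdhesionTable", "data.frame"),
            fractions = setNames(as.numeric(fr), names(fr)),
            n_dropped = sum(dropped))
}

#' Per-class fractions of an adhesion table
#'
#' @param x an `AdhesionTable` from [classify_adhesions()].
#' @return Named numeric vector (nascent, mature, fibrillar).
#' @export
adhesion_fractions <- function(x) attr(x, "fractions")
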