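#' Multi-channel time-lapse image stack
#'
#' Container for a registered multi-channel movie. Pixels are stored as a
#' 4-D numeric array indexed `(time, channel, row, col)`; intensities are
#' promoted to double on construction. Spatial calibration is carried as
#' micrometres per pixel and seconds per frame.
#'
#' @param pixels 4-D numeric array `(time, channel, row, col)`, non-negative.
#' @param channel_names character vector naming the channels, in order.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param frame_interval_s seconds per frame (> 0).
#'
#' @return An object of class `ChannelStack`.
#' @export
channel_stack <- function(pixels, channel_names, pixel_size_um,
                          frame_interval_s) {
  pixels <- unclass(pixels)
  if (length(dim(pixels)) != 4L) {
    stop("pixels must be a 4-D (time, channel, row, col) array")
  }
  if (dim(pixels)[2L] != length(channel_names)) {
    stop("channel_names length must match the channel dimension")
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be finite and positive")
  }
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0) {
    stop("frame_interval_s must be finite and positive")
  }
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, channel_names = as.character(channel_names),
         pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s),
    class = "ChannelStack"
  )
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "ChannelStack: %d frame(s) x %d channel(s) [%s], %d x %d px, %.4g um/px, %.4g s/frame\n",
    d[1], d[2], paste(x$channel_names, collapse = ", "), d[3], d[4],
    x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @export
dim.ChannelStack <- function(x) dim(x$pixels)

# Extract one frame of one channel as a (row, col) matrix.
#' Extract a single channel frame
#'
#' @param stack a [channel_stack()].
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return Numeric `(row, col)` matrix.
#' @export
get_frame <- function(stack, frame, channel) {
  stopifnot(inherits(stack, "ChannelStack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  stack$pixels[frame, channel, , ]
}

#' Binary mask with spatial calibration
#'
#' @param pixels logical `(row, col)` matrix.
#' @param pixel_size_um micrometres per pixel.
#' @return An object of class `BinaryMask`.
#' @export
binary_mask <- function(pixels, pixel_size_um = 1) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "BinaryMask")
}

#' Read a multi-page TIFF into a ChannelStack
#'
#' Pages are de-interleaved into `(time, channel)` order. The default
#' `"channel-fastest"` convention assumes pages cycle through the channels
#' within each timepoint (the common microscope export order);
#' `"time-fastest"` assumes all frames of channel 1 precede channel 2, etc.
#'
#' @param path path to a multi-page TIFF file.
#' @param channel_names labels for the channels; their number must divide
#'   the page count.
#' @param pixel_size_um,frame_interval_s spatial and temporal calibration.
#' @param interleave `"channel-fastest"` (default) or `"time-fastest"`.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, channel_names, pixel_size_um, frame_interval_s,
                       interleave = c("channel-fastest", "time-fastest")) {
  interleave <- match.arg(interleave)
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channel_names)
  if (length(pages) %% n_ch != 0L) {
    stop(sprintf("page count (%d) not divisible by channel count (%d)",
                 length(pages), n_ch))
  }
  n_t <- length(pages) %/% n_ch
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  px <- array(0, dim = c(n_t, n_ch, h, w))
  for (p in seq_along(pages)) {
    if (interleave == "channel-fastest") {
      t <- ((p - 1L) %/% n_ch) + 1L
      ch <- ((p - 1L) %% n_ch) + 1L
    } else {
      ch <- ((p - 1L) %/% n_t) + 1L
      t <- ((p - 1L) %% n_t) + 1L
    }
    px[t, ch, , ] <- as.numeric(pages[[p]])
  }
  channel_stack(px, channel_names, pixel_size_um, frame_interval_s)
}

#' Write a ChannelStack to a multi-page TIFF
#'
#' Pages are written in the same interleave convention that [read_stack()]
#' reads, as 16-bit unsigned integers. Integer-valued pixel data in
#' `[0, 65535]` round-trips exactly.
#'
#' @param stack a [channel_stack()].
#' @param path output file path.
#' @param interleave page ordering convention, see [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path,
                        interleave = c("channel-fastest", "time-fastest")) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(stack, "ChannelStack"))
  d <- dim(stack$pixels)
  mx <- 65535
  if (max(stack$pixels) > mx || min(stack$pixels) < 0) {
    stop("pixel values outside [0, 65535] cannot be written as 16-bit TIFF")
  }
  pages <- vector("list", d[1L] * d[2L])
  p <- 0L
  if (interleave == "channel-fastest") {
    for (t in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
      p <- p + 1L
      pages[[p]] <- round(stack$pixels[t, ch, , ]) / mx
    }
  } else {
    for (ch in seq_len(d[2L])) for (t in seq_len(d[1L])) {
      p <- p + 1L
      pages[[p]] <- round(stack$pixels[t, ch, , ]) / mx
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a table of records as CSV
#'
#' UTF-8, header row, `.` decimal separator, no row names.
#'
#' @param rows a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}

#' Default pipeline configuration
#'
#' Returns the full set of stage parameters with their defaults; values
#' stated by the underlying quantitative protocol (denoise sigma, kymograph
#' width, near-edge pixel count, detector scale and quality, linking
#' distances, track filters, adhesion bins) are the defaults here.
#'
#' @param ... named overrides, e.g. `ratio = list(denoise_sigma = 1)`.
#' @return A nested list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    io = list(interleave = "channel-fastest"),
    ratio = list(denoise_sigma = 0.5, edge_depth_um = 2.4,
                 otsu_channel = "reference", min_object_px = 50),
    fret = list(alpha = NA_real_, beta = NA_real_),
    kymo = list(width_px = 3, v_stall_um_min = 0.5, min_run_frames = 3,
                n_events = 5),
    xcorr = list(presmooth_sigma = 1, near_edge_px = 4,
                 series = "displacement"),
    porosity = list(blur_sigma = 0.5, tophat_radius = 15, min_area_px = 5,
                    connectivity = 4, invert = FALSE),
    measure = list(k_sd = 1.5, band_px = 5),
    adhesions = list(bins = c(0.05, 0.20, 1.75)),
    track = list(diameter_um = 25, quality_threshold = 0.08,
                 max_link_um = 50, gap_close_um = 50, max_frame_gap = 3,
                 min_duration_min = 60, min_span_um = 18),
    provenance = list()
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && !is.null(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults from
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
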