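# Actin meshwork porosity and pore sizes from electron micrographs:
# Gaussian blur, white top-hat, deterministic k-means binarisation,
# porosity and void-component statistics.
#
# The pipeline operates on filament-bright images; electron micrographs
# presented in inverted contrast (dark filaments) must be flipped with
# `invert = TRUE` in [meshwork_analysis()].

#' Preprocess an EM image for binarisation
#'
#' Gaussian blur followed by a white top-hat (image minus its
#' morphological opening with a disc), which extracts linear features
#' thinner than the structuring element and maps flat or slowly varying
#' background to approximately zero.
#'
#' @param image 2-D intensity matrix, non-constant.
#' @param blur_sigma Gaussian sigma, px (default 0.5).
#' @param tophat_radius disc radius, px (>= 1, default 15); must exceed
#'   the filament width but stay below the pore scale.
#' @return Non-negative filtered matrix.
#' @export
preprocess_em <- function(image, blur_sigma = 0.5, tophat_radius = 15) {
  if (tophat_radius < 1) stop("tophat_radius must be >= 1")
  if (diff(range(image)) <= 0) stop("constant image")
  img <- .gauss_blur2d(image, blur_sigma)
  brush <- EBImage::makeBrush(2L * round(tophat_radius) + 1L, shape = "disc")
  # EBImage grayscale morphology operates on the [0, 1] range; scale in
  # and out so the transform is correct for arbitrary intensity units
  r <- range(img)
  u <- (img - r[1L]) / diff(r)
  th <- EBImage::whiteTopHat(EBImage::Image(u), brush)
  pmax(as.matrix(th), 0) * diff(r)
}

#' Binarise by 1-D k-means on pixel intensities
#'
#' Two-cluster Lloyd k-means with deterministic initialisation at the
#' 25th and 75th intensity percentiles; the cluster with the higher mean
#' is foreground.
#'
#' @param image 2-D intensity matrix with >= 2 distinct values.
#' @param pixel_size_um calibration stored on the mask.
#' @return A [binary_mask()] of the foreground (filaments).
#' @export
binarize_kmeans <- function(image, pixel_size_um = 1) {
  x <- as.numeric(image)
  q <- quantile(x, c(0.25, 0.75))
  if (diff(range(x)) <= 0 || q[1L] == q[2L]) {
    stop("degenerate intensity distribution; cannot form two clusters")
  }
  km <- kmeans(x, centers = matrix(q, 2L, 1L), iter.max = 100L,
               algorithm = "Lloyd")
  fg_cluster <- which.max(km$centers)
  binary_mask(matrix(km$cluster == fg_cluster, nrow(image), ncol(image)),
              pixel_size_um)
}

#' Porosity of a meshwork mask
#'
#' Fraction of ROI pixels that are background (devoid of filaments).
#'
#' @param mask foreground [binary_mask()].
#' @param roi optional ROI [binary_mask()]; full image by default.
#' @return Fraction in `[0, 1]`.
#' @export
porosity <- function(mask, roi = NULL) {
  fg <- mask$pixels
  r <- if (is.null(roi)) matrix(TRUE, nrow(fg), ncol(fg)) else roi$pixels
  if (!any(r)) stop("empty ROI")
  mean(!fg[r])
}

#' Pore (void) sizes of a meshwork mask
#'
#' Connected components of the inverted foreground mask within the ROI.
#' Components touching the ROI border are excluded from the size
#' statistics (their true area is unbounded); components smaller than
#' `min_area_px` are discarded.
#'
#' @param mask foreground [binary_mask()].
#' @param roi optional ROI [binary_mask()]; full image by default.
#' @param min_area_px smallest pore retained, px^2.
#' @param connectivity 4 or 8.
#' @param nm_per_px optional calibration; adds `area_nm2`.
#' @return List with `areas_px2` (sorted decreasing), `mean_area_px2`
#'   (`NA` if no pore survives), `n_pores`, and `areas_nm2` when
#'   calibrated.
#' @export
pore_sizes <- function(mask, roi = NULL, min_area_px = 5L,
                       connectivity = 4L, nm_per_px = NULL) {
  fg <- mask$pixels
  h <- nrow(fg); w <- ncol(fg)
  r <- if (is.null(roi)) matrix(TRUE, h, w) else roi$pixels
  if (!any(r)) stop("empty ROI")
  voids <- (!fg) & r
  lab <- .label_components(voids, as.integer(connectivity))
  # ROI border: roi pixels adjacent to non-roi or the image border
  inner <- r
  inner[1L, ] <- FALSE; inner[h, ] <- FALSE
  inner[, 1L] <- FALSE; inner[, w] <- FALSE
  shrunk <- inner &
    .shift_int(r, 1L, 0L, FALSE) & .shift_int(r, -1L, 0L, FALSE) &
    .shift_int(r, 0L, 1L, FALSE) & .shift_int(r, 0L, -1L, FALSE)
  border <- r & !shrunk
  touching <- unique(lab[border & lab > 0L])
  areas <- tabulate(lab[lab > 0L])
  keep <- setdiff(which(areas >= min_area_px), touching)
  out_areas <- sort(areas[keep], decreasing = TRUE)
  res <- list(areas_px2 = out_areas,
              mean_area_px2 = if (length(out_areas)) mean(out_areas) else NA_real_,
              n_pores = length(out_areas))
  if (!is.null(nm_per_px)) {
    res$areas_nm2 <- out_areas * nm_per_px^2
    res$mean_area_nm2 <- res$mean_area_px2 * nm_per_px^2
  }
  res
}

#' Full meshwork porosity analysis of an EM image
#'
#' Chains [preprocess_em()], [binarize_kmeans()], [porosity()] and
#' [pore_sizes()].
#'
#' @param image grayscale EM matrix (filament-bright unless `invert`).
#' @param blur_sigma,tophat_radius see [preprocess_em()].
#' @param roi optional ROI [binary_mask()].
#' @param min_area_px,connectivity see [pore_sizes()].
#' @param invert flip contrast first (for micrographs presented with dark
#'   filaments on a bright background).
#' @param nm_per_px optional calibration.
#' @return Object of class `MeshworkResult`: `foreground_mask`,
#'   `porosity`, `pore_areas_px2`, `mean_pore_area_px2`, `n_pores`,
#'   `params` (and `_nm2` fields when calibrated).
#' @export
meshwork_analysis <- function(image, blur_sigma = 0.5, tophat_radius = 15,
                              roi = NULL, min_area_px = 5L,
                              connectivity = 4L, invert = FALSE,
                              nm_per_px = NULL) {
  if (invert) image <- max(image) - image
  prep <- preprocess_em(image, blur_sigma, tophat_radius)
  mask <- binarize_kmeans(prep)
  p <- porosity(mask, roi)
  ps <- pore_sizes(mask, roi, min_area_px, connectivity, nm_per_px)
  structure(list(foreground_mask = mask, porosity = p,
                 pore_areas_px2 = ps$areas_px2,
                 mean_pore_area_px2 = ps$mean_area_px2,
                 n_pores = ps$n_pores,
                 mean_pore_area_nm2 = ps$mean_area_nm2,
                 params = list(blur_sigma = blur_sigma,
                               tophat_radius = tophat_radius,
                               min_area_px = min_area_px,
                               connectivity = connectivity,
                               invert = invert, nm_per_px = nm_per_px)),
            class = "MeshworkResult")
}

#' @export
print.MeshworkResult <- function(x, ...) {
  cat(sprintf("MeshworkResult: porosity %.3f, %d pores, mean pore %.1f px^2\n",
              x$porosity, x$n_pores, x$mean_pore_area_px2))
  invisible(x)
}
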