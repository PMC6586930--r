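#' Calibrated fluorescence image
#'
#' A 2-D grid of non-negative intensities together with its physical pixel
#' size. All geometric parameters of the analysis (compartment areas in
#' \eqn{\mu m^2}, band widths in \eqn{\mu m}) are converted to pixel units
#' through this calibration.
#'
#' @param pixels numeric matrix of intensities (rows x cols), all values >= 0.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param bit_depth nominal acquisition bit depth, 8 or 16 (metadata only;
#'   intensities are stored as given).
#'
#' @return an object of class `calibrated_image` with fields `pixels`,
#'   `pixel_size_um` and `bit_depth`.
#' @export
#' @examples
#' img <- calibrated_image(matrix(0, 64, 64), pixel_size_um = 0.1)
#' dim(img$pixels)
calibrated_image <- function(pixels, pixel_size_um, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have positive width and height", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Two-channel image (marker + protein of interest)
#'
#' Pairs the compartment-marker channel (used for segmentation) with the
#' protein-of-interest channel (whose intensity is quantified inside the
#' segmented compartments). Both channels must share dimensions and pixel
#' calibration.
#'
#' @param marker,protein [calibrated_image()] objects of identical geometry.
#' @return an object of class `two_channel_image`.
#' @export
two_channel_image <- function(marker, protein) {
  stopifnot(inherits(marker, "calibrated_image"),
            inherits(protein, "calibrated_image"))
  if (!identical(dim(marker$pixels), dim(protein$pixels))) {
    stop("marker and protein channels must share dimensions", call. = FALSE)
  }
  if (marker$pixel_size_um != protein$pixel_size_um) {
    stop("marker and protein channels must share pixel_size_um", call. = FALSE)
  }
  structure(list(marker = marker, protein = protein),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, %.4g um/px\n",
              nrow(x$marker$pixels), ncol(x$marker$pixels),
              x$marker$pixel_size_um))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Axis-aligned rectangular ROI restricting the analysis to the cell area
#' containing the compartments of interest. The conventional analysis window
#' is 300 x 300 pixels. Coordinates are 1-based (row, col) with closed
#' extents: the ROI covers rows `origin_row .. origin_row + height_px - 1`.
#'
#' @param origin_row,origin_col 1-based integer offsets of the top-left pixel.
#' @param height_px,width_px positive integer extents (default 300 x 300).
#' @return an object of class `roi`.
#' @export
roi <- function(origin_row = 1L, origin_col = 1L,
                height_px = 300L, width_px = 300L) {
  vals <- c(origin_row, origin_col, height_px, width_px)
  if (any(vals != as.integer(vals)) || origin_row < 1L || origin_col < 1L ||
      height_px < 1L || width_px < 1L) {
    stop("ROI origin must be >= 1 and extents positive integers",
         call. = FALSE)
  }
  structure(list(origin_row = as.integer(origin_row),
                 origin_col = as.integer(origin_col),
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> origin (%d, %d), %d x %d px\n",
              x$origin_row, x$origin_col, x$height_px, x$width_px))
  invisible(x)
}

#' Crop an image to a region of interest
#'
#' Extracts the ROI rectangle. An ROI extending beyond the image bounds is
#' rejected rather than silently clipped.
#'
#' @param image a [calibrated_image()].
#' @param roi an [roi()] fully contained in the image.
#' @return a [calibrated_image()] of the ROI extents with unchanged
#'   calibration.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(image, "calibrated_image"), inherits(roi, "roi"))
  r2 <- roi$origin_row + roi$height_px - 1L
  c2 <- roi$origin_col + roi$width_px - 1L
  if (r2 > nrow(image$pixels) || c2 > ncol(image$pixels)) {
    stop(sprintf(
      "ROI [%d:%d, %d:%d] exceeds image bounds (%d x %d)",
      roi$origin_row, r2, roi$origin_col, c2,
      nrow(image$pixels), ncol(image$pixels)), call. = FALSE)
  }
  calibrated_image(image$pixels[roi$origin_row:r2, roi$origin_col:c2,
                                drop = FALSE],
                   image$pixel_size_um, image$bit_depth)
}

#' Convert a physical area to a pixel count
#'
#' @param area_um2 area in square micrometres (> 0).
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @return real-valued pixel count `area_um2 / pixel_size_um^2`.
#' @export
#' @examples
#' um2_to_px_area(1.2, 0.1) # 120 px, the endosome-scale default
um2_to_px_area <- function(area_um2, pixel_size_um) {
  if (!is.numeric(area_um2) || any(area_um2 <= 0) ||
      !is.numeric(pixel_size_um) || any(pixel_size_um <= 0)) {
    stop("area and pixel size must be positive", call. = FALSE)
  }
  area_um2 / pixel_size_um^2
}
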