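# TIFF planes are stored as raw sample values; the tiff package exchanges
# [0,1]-scaled data, so integer intensities are divided by (2^bits - 1) on
# write and read back with as.is = TRUE, which round-trips them bit-exactly.

read_tiff_planes <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  planes <- list()
  for (pg in pages) {
    if (length(dim(pg)) == 3L) {
      for (k in seq_len(dim(pg)[3L])) planes[[length(planes) + 1L]] <- pg[, , k]
    } else {
      planes[[length(planes) + 1L]] <- pg
    }
  }
  attr(planes, "info") <- attributes(pages[[1L]])
  planes
}

# Pixel size from TIFF resolution tags (pixels per cm/inch), if present.
pixel_size_from_info <- function(info) {
  xres <- info[["x.resolution"]]
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  unit <- info[["resolution.unit"]]
  per_um <- switch(as.character(unit %||% "inch"),
                   "cm" = xres / 1e4, "inch" = xres / 25400, NULL)
  if (is.null(per_um) || per_um <= 0) return(NULL)
  1 / per_um
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a two-channel TIFF as a calibrated image pair
#'
#' Reads a multi-page or multi-channel TIFF and returns the selected marker
#' and protein planes with the supplied pixel calibration. Intensities are
#' preserved bit-exactly. Pixel size is taken from the `pixel_size_um`
#' argument; TIFF resolution metadata is used only when the argument is
#' omitted, and a warning is issued when both are available and disagree.
#'
#' @param path path to an 8- or 16-bit unsigned TIFF with at least two
#'   planes/channels.
#' @param marker_index,protein_index 1-based plane indices of the
#'   compartment-marker and protein-of-interest channels (must differ).
#' @param pixel_size_um pixel edge length in micrometres; may be `NULL` if
#'   the file carries resolution metadata.
#' @param bit_depth nominal bit depth recorded on the returned images.
#' @return a [two_channel_image()].
#' @export
load_two_channel_tiff <- function(path, marker_index = 1L, protein_index = 2L,
                                  pixel_size_um = NULL, bit_depth = 16L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (marker_index == protein_index) {
    stop("marker and protein channel indices must differ", call. = FALSE)
  }
  planes <- read_tiff_planes(path)
  n <- length(planes)
  if (max(marker_index, protein_index) > n || min(marker_index, protein_index) < 1L) {
    stop(sprintf("file has %d plane(s); requested channels %d and %d",
                 n, marker_index, protein_index), call. = FALSE)
  }
  meta_ps <- pixel_size_from_info(attr(planes, "info"))
  if (is.null(pixel_size_um)) {
    if (is.null(meta_ps)) {
      stop("no pixel size supplied and none found in TIFF metadata",
           call. = FALSE)
    }
    pixel_size_um <- meta_ps
  } else if (!is.null(meta_ps) &&
             abs(meta_ps - pixel_size_um) > 1e-6 * pixel_size_um) {
    warning(sprintf(
      "supplied pixel size %.6g um/px overrides TIFF metadata %.6g um/px",
      pixel_size_um, meta_ps), call. = FALSE)
  }
  two_channel_image(
    calibrated_image(planes[[marker_index]], pixel_size_um, bit_depth),
    calibrated_image(planes[[protein_index]], pixel_size_um, bit_depth)
  )
}

#' Write matrices as a multi-page unsigned-integer TIFF
#'
#' Values are rounded to integers and must fit the requested bit depth;
#' reading the file back with [load_two_channel_tiff()] restores them
#' bit-exactly.
#'
#' @param planes a matrix or list of matrices (one per page).
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_planes <- function(planes, path, bit_depth = 16L) {
  if (is.matrix(planes)) planes <- list(planes)
  maxval <- 2^bit_depth - 1
  scaled <- lapply(planes, function(m) {
    m <- round(m)
    if (any(m < 0) || any(m > maxval)) {
      stop(sprintf("intensities outside [0, %d] cannot be stored at %d-bit",
                   maxval, bit_depth), call. = FALSE)
    }
    m / maxval
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' Read an ROI specification from a JSON file
#'
#' The file must contain the fields `origin_row`, `origin_col`, `height_px`,
#' `width_px` (1-based origin).
#'
#' @param path path to a JSON file.
#' @return an [roi()].
#' @export
roi_from_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("origin_row", "origin_col", "height_px", "width_px")
  if (!all(need %in% names(spec))) {
    stop("ROI JSON must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  roi(spec$origin_row, spec$origin_col, spec$height_px, spec$width_px)
}
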