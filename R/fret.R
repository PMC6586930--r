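# Ratiometric FRET quantification: background-subtracted YFP(FRET)/CFP
# ratio maps summarized over the whole cell, a band at the cell edge
# (plasma-membrane proximal), or segmented endomembrane compartments.

#' FRET input bundle
#'
#' @param cfp CFP-emission channel ([calibrated_image()], 480 nm).
#' @param yfp FRET-emission channel read in the YFP channel
#'   ([calibrated_image()], 530 nm); same geometry as `cfp`.
#' @param cell_mask logical matrix marking the (manually segmented) cell.
#' @param background_region logical matrix (or linear pixel indices) of a
#'   region outside the cell used for background estimation; must be
#'   non-empty and disjoint from the cell mask.
#' @param bin_factor integer >= 1; the published operating points are 2
#'   (early/recycling endosomes) and 3 (autophagosomes).
#' @param edge_band_um width of the cell-edge band in micrometres
#'   (default 1.67).
#' @return an object of class `fret_input`.
#' @export
fret_input <- function(cfp, yfp, cell_mask, background_region,
                       bin_factor = 1L, edge_band_um = 1.67) {
  stopifnot(inherits(cfp, "calibrated_image"), inherits(yfp, "calibrated_image"))
  if (!identical(dim(cfp$pixels), dim(yfp$pixels)) ||
      cfp$pixel_size_um != yfp$pixel_size_um) {
    stop("cfp and yfp channels must share geometry and calibration",
         call. = FALSE)
  }
  dims <- dim(cfp$pixels)
  if (!is.logical(cell_mask) || !identical(dim(cell_mask), dims)) {
    stop("cell_mask must be a logical matrix matching the channels",
         call. = FALSE)
  }
  if (is.logical(background_region)) {
    if (!identical(dim(background_region), dims)) {
      stop("background_region mask must match the channel geometry",
           call. = FALSE)
    }
    bg_idx <- which(background_region)
  } else {
    bg_idx <- as.integer(background_region)
    if (any(bg_idx < 1L | bg_idx > prod(dims))) {
      stop("background_region indices out of range", call. = FALSE)
    }
  }
  if (length(bg_idx) == 0L) stop("background region is empty", call. = FALSE)
  if (any(cell_mask[bg_idx])) {
    stop("background region must lie outside the cell mask", call. = FALSE)
  }
  if (bin_factor < 1 || bin_factor != as.integer(bin_factor)) {
    stop("bin_factor must be an integer >= 1", call. = FALSE)
  }
  if (edge_band_um <= 0) stop("edge_band_um must be positive", call. = FALSE)
  structure(list(cfp = cfp, yfp = yfp, cell_mask = cell_mask,
                 background_idx = bg_idx,
                 bin_factor = as.integer(bin_factor),
                 edge_band_um = as.numeric(edge_band_um)),
            class = "fret_input")
}

# calibrated_image-shaped object that may carry negative values
# (background-subtracted or binned intermediates).
signed_image <- function(pixels, pixel_size_um, bit_depth = 16L) {
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 bit_depth = bit_depth),
            class = "calibrated_image")
}

#' Subtract the mean background from a channel
#'
#' Every pixel is reduced by the mean intensity of the background region
#' (measured outside the cell). Resulting values may be negative; they are
#' not clamped, and a non-positive denominator is invalidated later in
#' [fret_ratio_map()].
#'
#' @param channel a [calibrated_image()].
#' @param background_region logical matrix or linear pixel indices
#'   (non-empty).
#' @return a calibrated image of the same geometry (possibly with negative
#'   values).
#' @export
subtract_background <- function(channel, background_region) {
  stopifnot(inherits(channel, "calibrated_image"))
  idx <- if (is.logical(background_region)) which(background_region)
         else as.integer(background_region)
  if (length(idx) == 0L) stop("background region is empty", call. = FALSE)
  bg <- mean(channel$pixels[idx])
  signed_image(channel$pixels - bg, channel$pixel_size_um, channel$bit_depth)
}

block_mean <- function(x, f) {
  nr <- (nrow(x) %/% f) * f
  nc <- (ncol(x) %/% f) * f
  if (nr < f || nc < f) stop("image smaller than one bin", call. = FALSE)
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- rep(seq_len(nr %/% f), each = f)
  ci <- rep(seq_len(nc %/% f), each = f)
  t(rowsum(t(rowsum(x, ri)), ci)) / f^2
}

#' Bin an image by block averaging
#'
#' Non-overlapping `factor x factor` blocks are reduced to their mean;
#' trailing rows/columns not filling a complete block are dropped. The
#' pixel size is multiplied by the factor.
#'
#' @param channel a [calibrated_image()].
#' @param factor integer >= 1 (1 is the identity).
#' @return a binned calibrated image.
#' @export
bin_image <- function(channel, factor) {
  stopifnot(inherits(channel, "calibrated_image"))
  if (factor < 1 || factor != as.integer(factor)) {
    stop("binning factor must be an integer >= 1", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(channel)
  signed_image(block_mean(channel$pixels, factor),
               channel$pixel_size_um * factor, channel$bit_depth)
}

#' Cell-edge band mask
#'
#' The band is the cell mask minus its morphological erosion by a disc of
#' radius `round(band_um / pixel_size_um)` pixels, i.e. an isotropic rim of
#' that width along the cell periphery. The band is always a subset of the
#' cell mask, and band plus eroded interior reconstitute the mask exactly.
#' A cell thinner than twice the band collapses to the entire cell.
#'
#' @param cell_mask logical matrix.
#' @param band_um band width in micrometres (default 1.67).
#' @param pixel_size_um pixel edge length in micrometres.
#' @return logical matrix of the band.
#' @export
edge_band_mask <- function(cell_mask, band_um = 1.67, pixel_size_um) {
  if (!is.logical(cell_mask) || !any(cell_mask)) {
    stop("cell_mask must be a non-empty logical matrix", call. = FALSE)
  }
  w <- as.integer(round(band_um / pixel_size_um))
  if (w < 1L) {
    stop(sprintf(
      "band width %.3g um rounds to 0 px at %.3g um/px; use a finer pixel size",
      band_um, pixel_size_um), call. = FALSE)
  }
  brush <- EBImage::makeBrush(2L * w + 1L, "disc")
  eroded <- EBImage::imageData(EBImage::erode(cell_mask + 0, brush)) > 0.5
  cell_mask & !eroded
}

#' Per-pixel background-subtracted YFP/CFP FRET ratio map
#'
#' Both channels are background-subtracted (per-channel mean over the
#' background region), binned by `bin_factor`, and divided per pixel
#' (YFP / CFP). Pixels outside the (binned) cell mask, or whose CFP
#' denominator is at or below a small positive floor (`1e-6` of the binned
#' CFP maximum), are marked invalid and excluded from all summaries.
#'
#' @param input a [fret_input()].
#' @return an object of class `ratio_map`: `ratio` (matrix, `NA` at invalid
#'   pixels), `valid_mask`, `cell_mask` (binned), `pixel_size_um`,
#'   `bin_factor` and the per-channel background means.
#' @export
fret_ratio_map <- function(input) {
  stopifnot(inherits(input, "fret_input"))
  cfp_bs <- subtract_background(input$cfp, input$background_idx)
  yfp_bs <- subtract_background(input$yfp, input$background_idx)
  f <- input$bin_factor
  cfp_b <- bin_image(cfp_bs, f)$pixels
  yfp_b <- bin_image(yfp_bs, f)$pixels
  mask_b <- if (f == 1L) input$cell_mask else block_mean(input$cell_mask + 0, f) >= 0.5
  eps <- 1e-6 * max(cfp_b)
  valid <- mask_b & cfp_b > max(eps, 0)
  if (!any(valid)) {
    stop("no valid pixels in the ratio map (check cell mask and CFP signal)",
         call. = FALSE)
  }
  ratio <- matrix(NA_real_, nrow(cfp_b), ncol(cfp_b))
  ratio[valid] <- yfp_b[valid] / cfp_b[valid]
  structure(list(ratio = ratio, valid_mask = valid, cell_mask = mask_b,
                 pixel_size_um = input$cfp$pixel_size_um * f,
                 bin_factor = f,
                 background_cfp = mean(input$cfp$pixels[input$background_idx]),
                 background_yfp = mean(input$yfp$pixels[input$background_idx])),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  v <- x$ratio[x$valid_mask]
  cat(sprintf("<ratio_map> %d x %d px (bin %d, %.4g um/px), %d valid pixel(s)\n",
              nrow(x$ratio), ncol(x$ratio), x$bin_factor, x$pixel_size_um,
              sum(x$valid_mask)))
  cat(sprintf("  ratio: mean %.4g, range [%.4g, %.4g]\n",
              mean(v), min(v), max(v)))
  invisible(x)
}

#' Mean FRET ratio over a region
#'
#' Mean of the ratio over the valid pixels inside the region. With labeled
#' compartments a per-region vector is returned; a region containing no
#' valid pixel is reported as `NA` (missing), not 0.
#'
#' @param map a [fret_ratio_map()] result.
#' @param region logical matrix matching the map, or a
#'   [segment_compartments()] result on the same (binned) geometry.
#' @return a single mean, or a named numeric vector per compartment.
#' @export
region_mean_ratio <- function(map, region) {
  stopifnot(inherits(map, "ratio_map"))
  if (inherits(region, "labeled_compartments")) {
    if (!identical(dim(region$label_map), dim(map$ratio))) {
      stop("compartments and ratio map must share geometry", call. = FALSE)
    }
    k <- count_compartments(region)
    out <- rep(NA_real_, k)
    for (i in seq_len(k)) {
      sel <- region$label_map == i & map$valid_mask
      if (any(sel)) out[i] <- mean(map$ratio[sel])
    }
    names(out) <- seq_len(k)
    return(out)
  }
  if (!is.logical(region) || !identical(dim(region), dim(map$ratio))) {
    stop("region must be a logical matrix matching the ratio map",
         call. = FALSE)
  }
  sel <- region & map$valid_mask
  if (!any(sel)) {
    warning("region contains no valid ratio pixel; returning NA")
    return(NA_real_)
  }
  mean(map$ratio[sel])
}

#' Whole-cell / edge-band / compartment FRET summary
#'
#' Convenience wrapper computing the ratio map and its mean over the whole
#' cell, over the cell-edge band, and (optionally) over labeled
#' compartments.
#'
#' @param input a [fret_input()].
#' @param compartments optional [segment_compartments()] result on the
#'   binned geometry.
#' @return a list with the `map` and a `summary` data.frame
#'   (columns `region`, `mean_ratio`, `n_pixels`).
#' @export
fret_summary <- function(input, compartments = NULL) {
  map <- fret_ratio_map(input)
  band <- edge_band_mask(map$cell_mask, input$edge_band_um, map$pixel_size_um)
  rows <- data.frame(
    region = c("whole_cell", "edge_band"),
    mean_ratio = c(region_mean_ratio(map, map$cell_mask),
                   region_mean_ratio(map, band)),
    n_pixels = c(sum(map$cell_mask & map$valid_mask),
                 sum(band & map$valid_mask)))
  if (!is.null(compartments)) {
    per <- region_mean_ratio(map, compartments)
    npx <- vapply(seq_along(per), function(i) {
      sum(compartments$label_map == i & map$valid_mask)
    }, integer(1))
    rows <- rbind(rows, data.frame(
      region = paste0("compartment_", seq_along(per)),
      mean_ratio = as.numeric(per), n_pixels = npx))
  }
  list(map = map, summary = rows)
}
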