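#' Segmentation parameters
#'
#' Controls the compartment-segmentation pipeline applied to the marker
#' channel: Gaussian smoothing, binarization, morphological closing, hole
#' filling and small-object rejection.
#'
#' @param gaussian_sigma_px smoothing scale in pixels (>= 0; 0 disables
#'   smoothing). Default 1, a typical confocal blur at endosome scale.
#' @param threshold_method `"otsu"` (automatic histogram split on the
#'   smoothed image) or `"fixed"`.
#' @param fixed_threshold intensity used when `threshold_method = "fixed"`;
#'   pixels strictly above it are foreground.
#' @param closing_radius_px disc radius of the morphological closing (>= 0;
#'   0 disables closing).
#' @param min_area_px objects smaller than this pixel count are discarded
#'   (>= 1). The cutoff for "very small" debris is deliberately small and
#'   prominently configurable.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma_px = 1.0,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                closing_radius_px = 1L,
                                min_area_px = 4L) {
  threshold_method <- match.arg(threshold_method)
  if (gaussian_sigma_px < 0) stop("gaussian_sigma_px must be >= 0", call. = FALSE)
  if (closing_radius_px < 0 || closing_radius_px != as.integer(closing_radius_px)) {
    stop("closing_radius_px must be a non-negative integer", call. = FALSE)
  }
  if (min_area_px < 1 || min_area_px != as.integer(min_area_px)) {
    stop("min_area_px must be a positive integer", call. = FALSE)
  }
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || !is.numeric(fixed_threshold))) {
    stop("fixed_threshold must be given with threshold_method = 'fixed'",
         call. = FALSE)
  }
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 closing_radius_px = as.integer(closing_radius_px),
                 min_area_px = as.integer(min_area_px)),
            class = "segmentation_params")
}

# 8-connected component labeling by vectorized min-label propagation:
# every foreground pixel starts with its own (column-major) index and
# repeatedly takes the minimum over its 8-neighbourhood until stable.
# Kept in-package so connectivity is exactly the ImageJ particle-analysis
# convention (8-connected).
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(out)
  lab <- matrix(Inf, nr, nc)
  lab[fg] <- fg
  shift <- function(m, dr, dc) {
    res <- matrix(Inf, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    res
  }
  repeat {
    new <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      new <- pmin(new, shift(lab, dr, dc))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[fg]))
  out[fg] <- match(lab[fg], ids)
  out
}

#' Segment endomembrane compartments from the marker channel
#'
#' Applies, in fixed order: (1) Gaussian smoothing, (2) binarization (pixels
#' strictly above the threshold are foreground), (3) morphological closing
#' with a disc, (4) hole filling, (5) 8-connected component labeling,
#' (6) removal of components smaller than `min_area_px`, (7) relabeling to
#' consecutive ids (ordered by first pixel in column-major raster order).
#' Closing precedes hole filling so that gaps are bridged before holes are
#' filled. A constant image under Otsu thresholding yields zero compartments.
#'
#' @param marker a [calibrated_image()] (the compartment-marker channel,
#'   usually already cropped to the ROI).
#' @param params a [segmentation_params()].
#' @return an object of class `labeled_compartments` with fields
#'   `label_map` (integer matrix, 0 = background, 1..K = compartments),
#'   `mask` (the refined binary foreground before labeling), `areas_px`
#'   (per-label pixel counts), `pixel_size_um` and `params`.
#' @export
segment_compartments <- function(marker, params = segmentation_params()) {
  stopifnot(inherits(marker, "calibrated_image"),
            inherits(params, "segmentation_params"))
  s <- marker$pixels
  if (params$gaussian_sigma_px > 0) {
    s <- EBImage::imageData(EBImage::gblur(s, sigma = params$gaussian_sigma_px))
  }
  if (params$threshold_method == "otsu") {
    lo <- min(s); hi <- max(s)
    if (hi <= lo) {
      fg <- matrix(FALSE, nrow(s), ncol(s))
    } else {
      t01 <- EBImage::otsu((s - lo) / (hi - lo), range = c(0, 1), levels = 256)
      fg <- s > lo + t01 * (hi - lo)
    }
  } else {
    fg <- s > params$fixed_threshold
  }
  if (any(fg) && params$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius_px + 1L, "disc")
    fg <- EBImage::imageData(EBImage::closing(fg + 0, brush)) > 0.5
  }
  if (any(fg)) {
    fg <- EBImage::imageData(EBImage::fillHull(fg + 0)) > 0.5
  }
  lab <- label_components_8(fg)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= params$min_area_px)
    lab[] <- match(lab, keep, nomatch = 0L)
    lab[is.na(lab)] <- 0L
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  structure(list(label_map = lab, mask = lab > 0L,
                 areas_px = as.integer(areas),
                 pixel_size_um = marker$pixel_size_um,
                 params = params),
            class = "labeled_compartments")
}

#' Number of segmented compartments
#'
#' @param labels a [segment_compartments()] result.
#' @return integer count K of distinct non-background labels.
#' @export
count_compartments <- function(labels) {
  stopifnot(inherits(labels, "labeled_compartments"))
  length(labels$areas_px)
}

#' @export
print.labeled_compartments <- function(x, ...) {
  cat(sprintf("<labeled_compartments> %d compartment(s) on %d x %d px (%.4g um/px)\n",
              count_compartments(x), nrow(x$label_map), ncol(x$label_map),
              x$pixel_size_um))
  if (length(x$areas_px)) {
    cat(sprintf("  area_px: median %.0f, range [%d, %d]\n",
                stats::median(x$areas_px), min(x$areas_px), max(x$areas_px)))
  }
  invisible(x)
}

#' Per-compartment geometry table
#'
#' @param labels a [segment_compartments()] result.
#' @return data.frame with columns `id`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`.
#' @export
compartment_table <- function(labels) {
  stopifnot(inherits(labels, "labeled_compartments"))
  k <- count_compartments(labels)
  if (k == 0L) {
    return(data.frame(id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  }
  idx <- which(labels$label_map > 0L)
  lid <- labels$label_map[idx]
  rows <- (idx - 1L) %% nrow(labels$label_map) + 1L
  cols <- (idx - 1L) %/% nrow(labels$label_map) + 1L
  data.frame(
    id = seq_len(k),
    area_px = labels$areas_px,
    area_um2 = labels$areas_px * labels$pixel_size_um^2,
    centroid_row = as.numeric(tapply(rows, lid, mean)),
    centroid_col = as.numeric(tapply(cols, lid, mean))
  )
}
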