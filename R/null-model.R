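#' Pseudo-compartment parameters
#'
#' Settings for the randomized null model: disks of compartment-like size
#' are dropped uniformly at random inside the ROI, so that protein intensity
#' measured in them estimates the colocalization expected by chance. The
#' published operating points are `n = 1000`, `area_um2 = 1.2` for endosomes
#' and autophagosomes, and `n = 10`, `area_um2 = 9.2` for trans-Golgi.
#'
#' @param n number of pseudo-compartments (>= 0).
#' @param area_um2 target area of each pseudo-compartment in \eqn{\mu m^2}.
#' @param seed optional RNG seed for reproducible placement.
#' @param allow_overlap may pseudo-compartments overlap each other? The
#'   default `TRUE` matches an unconstrained "by chance" null;
#'   `FALSE` enables rejection-sampled non-overlapping placement for
#'   sensitivity analysis.
#' @return an object of class `pseudo_compartment_params`.
#' @export
pseudo_compartment_params <- function(n = 1000L, area_um2 = 1.2,
                                      seed = NULL, allow_overlap = TRUE) {
  if (n < 0 || n != as.integer(n)) stop("n must be a non-negative integer",
                                        call. = FALSE)
  if (!is.numeric(area_um2) || area_um2 <= 0) {
    stop("area_um2 must be positive", call. = FALSE)
  }
  structure(list(n = as.integer(n), area_um2 = as.numeric(area_um2),
                 seed = seed, allow_overlap = isTRUE(allow_overlap)),
            class = "pseudo_compartment_params")
}

# Integer pixel offsets of a rasterized disk: all (dr, dc) with
# dr^2 + dc^2 <= radius^2.
disk_offsets <- function(radius_px) {
  d <- -radius_px:radius_px
  g <- expand.grid(dr = d, dc = d)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

#' Generate randomized pseudo-compartments inside an ROI
#'
#' Each pseudo-compartment is a rasterized disk of radius
#' `round(sqrt(area_px / pi))` pixels, where `area_px` is the requested area
#' converted through the pixel calibration. Centers are drawn uniformly at
#' random over all integer pixel positions that keep the disk fully inside
#' the ROI. Placement is reproducible given the seed.
#'
#' @param roi_shape integer vector `c(height_px, width_px)` of the ROI.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param params a [pseudo_compartment_params()].
#' @return an object of class `pseudo_compartments` with fields `regions`
#'   (data.frame: id, center_row, center_col, radius_px, area_px), `pixels`
#'   (list of linear pixel-index vectors into the ROI matrix), `radius_px`,
#'   `seed` and `mean_area_px`.
#' @export
generate_pseudo_compartments <- function(roi_shape, pixel_size_um, params) {
  stopifnot(inherits(params, "pseudo_compartment_params"))
  if (length(roi_shape) != 2L || any(roi_shape < 1L)) {
    stop("roi_shape must be c(height_px, width_px)", call. = FALSE)
  }
  nr <- as.integer(roi_shape[1L]); nc <- as.integer(roi_shape[2L])
  area_px <- um2_to_px_area(params$area_um2, pixel_size_um)
  radius <- as.integer(round(sqrt(area_px / pi)))
  if (2L * radius + 1L > min(nr, nc)) {
    stop(sprintf(
      "pseudo-compartment disk (radius %d px) does not fit in a %d x %d ROI",
      radius, nr, nc), call. = FALSE)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  offs <- disk_offsets(radius)
  n <- params$n
  if (n == 0L) {
    return(structure(list(
      regions = data.frame(id = integer(0), center_row = integer(0),
                           center_col = integer(0), radius_px = integer(0),
                           area_px = integer(0)),
      pixels = list(), radius_px = radius, requested_area_px = area_px,
      mean_area_px = NA_real_, seed = params$seed, roi_shape = c(nr, nc)),
      class = "pseudo_compartments"))
  }
  rmin <- radius + 1L; rmax <- nr - radius
  cmin <- radius + 1L; cmax <- nc - radius
  centers_r <- integer(n); centers_c <- integer(n)
  if (params$allow_overlap) {
    centers_r <- sample(rmin:rmax, n, replace = TRUE)
    centers_c <- sample(cmin:cmax, n, replace = TRUE)
  } else {
    placed <- 0L; attempts <- 0L; max_attempts <- 10000L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place non-overlapping pseudo-compartments; ",
             "reduce n or area", call. = FALSE)
      }
      cr <- sample(rmin:rmax, 1L); cc <- sample(cmin:cmax, 1L)
      if (placed > 0L &&
          any((centers_r[seq_len(placed)] - cr)^2 +
              (centers_c[seq_len(placed)] - cc)^2 <= (2L * radius)^2)) next
      placed <- placed + 1L
      centers_r[placed] <- cr; centers_c[placed] <- cc
    }
  }
  npx <- nrow(offs)
  pixels <- vector("list", n)
  for (i in seq_len(n)) {
    pixels[[i]] <- (centers_c[i] + offs$dc - 1L) * nr + (centers_r[i] + offs$dr)
  }
  structure(list(
    regions = data.frame(id = seq_len(n), center_row = centers_r,
                         center_col = centers_c, radius_px = radius,
                         area_px = npx),
    pixels = pixels, radius_px = radius, requested_area_px = area_px,
    mean_area_px = npx, seed = params$seed, roi_shape = c(nr, nc)),
    class = "pseudo_compartments")
}

#' @export
print.pseudo_compartments <- function(x, ...) {
  cat(sprintf(
    "<pseudo_compartments> %d disk(s), radius %d px, realized area %s px (requested %.1f px)\n",
    nrow(x$regions), x$radius_px,
    ifelse(is.na(x$mean_area_px), "NA", format(x$mean_area_px)),
    x$requested_area_px))
  invisible(x)
}
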