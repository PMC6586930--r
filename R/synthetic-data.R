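# Ground-truthed synthetic fixtures emulating the imaging regime the
# analysis was designed for: confocal cross sections of cells containing
# disk-like endomembrane compartments (endosome scale ~1.2 um^2) over a
# uniform background, with a controllable fraction of compartments
# enriched in the protein channel.

#' Parameters of the synthetic two-channel fixture
#'
#' Defaults describe the study conditions: a 300 x 300 px analysis window
#' at 0.1 um/px, ~50 well-separated disk compartments of ~1.2 um^2
#' (radius 0.55-0.70 um), high marker contrast (200 over background 10),
#' protein background 50 multiplied by `enrichment_factor` inside enriched
#' compartments, optional confocal-style PSF blur (Gaussian, sigma 1 px)
#' and additive Gaussian read noise (sd 2 intensity units) or Poisson shot
#' noise.
#'
#' @param image_size_px side length of the square image.
#' @param pixel_size_um pixel calibration in micrometres.
#' @param n_compartments number of disk compartments (>= 0), placed without
#'   overlap by rejection sampling.
#' @param radius_um_range min/max compartment radius in micrometres.
#' @param marker_background,marker_foreground marker-channel intensities.
#' @param protein_background protein-channel baseline intensity.
#' @param enrichment_factor e >= 1; protein level inside enriched
#'   compartments is `e * protein_background`.
#' @param fraction_enriched f in `[0, 1]`; `round(f * n)` compartments are
#'   enriched.
#' @param noise_model `"gaussian"` (additive, sd `noise_sd`) or `"poisson"`
#'   (shot noise on the expected intensity).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param psf_sigma_px Gaussian PSF blur applied to the noiseless structure
#'   (0 disables).
#' @param seed RNG seed; fixtures are fully reproducible from
#'   (params, seed).
#' @return an object of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size_px = 300L, pixel_size_um = 0.1,
                             n_compartments = 50L,
                             radius_um_range = c(0.55, 0.70),
                             marker_background = 10,
                             marker_foreground = 200,
                             protein_background = 50,
                             enrichment_factor = 10,
                             fraction_enriched = 0.5,
                             noise_model = c("gaussian", "poisson"),
                             noise_sd = 2,
                             psf_sigma_px = 1,
                             seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(image_size_px >= 8, pixel_size_um > 0, n_compartments >= 0,
            length(radius_um_range) == 2L, all(radius_um_range > 0),
            radius_um_range[1] <= radius_um_range[2],
            marker_background >= 0, marker_foreground >= 0,
            protein_background >= 0, enrichment_factor >= 1,
            fraction_enriched >= 0, fraction_enriched <= 1,
            noise_sd >= 0, psf_sigma_px >= 0)
  structure(as.list(environment()), class = "synthetic_params")
}

add_noise <- function(expected, model, sd) {
  noisy <- switch(model,
    gaussian = expected + stats::rnorm(length(expected), 0, sd),
    poisson = stats::rpois(length(expected), lambda = expected))
  m <- matrix(pmax(noisy, 0), nrow(expected), ncol(expected))
  m
}

#' Generate a ground-truthed two-channel colocalization fixture
#'
#' The marker channel is background plus `n` non-overlapping foreground
#' disks; the protein channel is its own background everywhere, multiplied
#' by the enrichment factor inside the `round(f * n)` enriched disks. Both
#' channels are optionally PSF-blurred, then noise is added. Deterministic
#' given the seed.
#'
#' @param params a [synthetic_params()].
#' @return a list with `image` (a [two_channel_image()]) and `truth`
#'   (data.frame: `id`, `center_row`, `center_col`, `radius_px`,
#'   `enriched`), plus the `params` used.
#' @export
generate_colocalization_fixture <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- as.integer(params$n_compartments)
  sz <- as.integer(params$image_size_px)
  radii <- if (n > 0) {
    as.integer(round(stats::runif(n, params$radius_um_range[1],
                                  params$radius_um_range[2]) /
                     params$pixel_size_um))
  } else integer(0)
  radii <- pmax(radii, 1L)
  if (n > 0 && 2L * max(radii) + 6L > sz) {
    stop("image too small to host the requested compartments", call. = FALSE)
  }
  # rejection-sampled non-overlapping placement with a small separation gap
  # so that PSF blur cannot merge neighbours
  gap <- 4L
  cr <- integer(n); cc <- integer(n)
  attempts <- 0L; max_attempts <- 20000L * max(n, 1L)
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place non-overlapping compartments; reduce n or radius",
           call. = FALSE)
    }
    i <- placed + 1L
    r <- radii[i]
    a <- sample((r + 2L):(sz - r - 1L), 1L)
    b <- sample((r + 2L):(sz - r - 1L), 1L)
    if (placed > 0L) {
      j <- seq_len(placed)
      if (any((cr[j] - a)^2 + (cc[j] - b)^2 <
              (radii[j] + r + gap)^2)) next
    }
    cr[i] <- a; cc[i] <- b; placed <- i
  }
  n_enriched <- as.integer(round(params$fraction_enriched * n))
  enriched <- rep(FALSE, n)
  if (n_enriched > 0L) enriched[sample.int(n, n_enriched)] <- TRUE

  marker0 <- matrix(params$marker_background, sz, sz)
  protein0 <- matrix(params$protein_background, sz, sz)
  for (i in seq_len(n)) {
    offs <- disk_offsets(radii[i])
    idx <- (cc[i] + offs$dc - 1L) * sz + (cr[i] + offs$dr)
    marker0[idx] <- params$marker_foreground
    if (enriched[i]) {
      protein0[idx] <- params$enrichment_factor * params$protein_background
    }
  }
  if (params$psf_sigma_px > 0) {
    marker0 <- EBImage::imageData(EBImage::gblur(marker0, params$psf_sigma_px))
    protein0 <- EBImage::imageData(EBImage::gblur(protein0, params$psf_sigma_px))
  }
  marker <- add_noise(marker0, params$noise_model, params$noise_sd)
  protein <- add_noise(protein0, params$noise_model, params$noise_sd)
  list(
    image = two_channel_image(
      calibrated_image(marker, params$pixel_size_um),
      calibrated_image(protein, params$pixel_size_um)),
    truth = data.frame(id = seq_len(n), center_row = cr, center_col = cc,
                       radius_px = radii, enriched = enriched),
    params = params
  )
}

#' Generate a ground-truthed FRET fixture
#'
#' Builds a CFP/YFP channel pair realizing a known true ratio: inside the
#' cell, `cfp = background + cfp_level` and
#' `yfp = background + true_ratio * cfp_level`; outside, both channels sit
#' at the background level. The cell is a centred rectangle and the
#' background region a frame along the image border. Deterministic given
#' the seed.
#'
#' @param true_ratio a positive constant or a positive matrix of per-pixel
#'   true ratios (its dimensions set the image size).
#' @param cfp_level CFP signal amplitude inside the cell.
#' @param background camera background level in both channels.
#' @param noise_sd additive Gaussian noise sd (0 for a noiseless fixture).
#' @param seed RNG seed.
#' @param size image side length when `true_ratio` is a constant.
#' @param pixel_size_um pixel calibration (default 0.334, so the standard
#'   1.67 um edge band is 5 px wide).
#' @param cell_margin_px margin between image border and cell rectangle.
#' @param bin_factor,edge_band_um forwarded to [fret_input()].
#' @return a list with `input` (a [fret_input()]) and `truth`
#'   (`true_ratio` matrix and the `cell_mask`).
#' @export
generate_fret_fixture <- function(true_ratio = 2, cfp_level = 1000,
                                  background = 100, noise_sd = 0,
                                  seed = NULL, size = 120L,
                                  pixel_size_um = 0.334,
                                  cell_margin_px = 15L,
                                  bin_factor = 1L, edge_band_um = 1.67) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(true_ratio)) {
    ratio <- true_ratio
    size <- nrow(ratio)
    if (ncol(ratio) != size) stop("true_ratio matrix must be square",
                                  call. = FALSE)
  } else {
    if (length(true_ratio) != 1L) {
      stop("true_ratio must be a constant or a matrix", call. = FALSE)
    }
    ratio <- matrix(true_ratio, size, size)
  }
  if (any(ratio <= 0)) stop("true ratios must be positive", call. = FALSE)
  m <- as.integer(cell_margin_px)
  if (2L * m + 10L > size) stop("cell margin too large for image", call. = FALSE)
  cell <- matrix(FALSE, size, size)
  cell[(m + 1L):(size - m), (m + 1L):(size - m)] <- TRUE
  bg_region <- matrix(FALSE, size, size)
  frame <- max(3L, m %/% 3L)
  bg_region[seq_len(frame), ] <- TRUE
  cfp <- matrix(background, size, size)
  yfp <- matrix(background, size, size)
  cfp[cell] <- background + cfp_level
  yfp[cell] <- background + ratio[cell] * cfp_level
  if (noise_sd > 0) {
    cfp <- cfp + stats::rnorm(length(cfp), 0, noise_sd)
    yfp <- yfp + stats::rnorm(length(yfp), 0, noise_sd)
  }
  cfp <- matrix(pmax(cfp, 0), size, size)
  yfp <- matrix(pmax(yfp, 0), size, size)
  input <- fret_input(
    cfp = calibrated_image(cfp, pixel_size_um),
    yfp = calibrated_image(yfp, pixel_size_um),
    cell_mask = cell, background_region = bg_region,
    bin_factor = bin_factor, edge_band_um = edge_band_um)
  list(input = input, truth = list(true_ratio = ratio, cell_mask = cell))
}
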