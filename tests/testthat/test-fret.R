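test_that("background subtraction removes the region mean", {
  ch <- calibrated_image(matrix(100, 20, 20), 0.334)
  bg <- matrix(FALSE, 20, 20); bg[1:3, 1:3] <- TRUE
  out <- subtract_background(ch, bg)
  expect_true(all(out$pixels == 0))

  px <- matrix(50, 10, 10); px[1, 1:3] <- c(10, 12, 14)
  ch2 <- calibrated_image(px, 0.334)
  out2 <- subtract_background(ch2, which(px < 20))
  expect_equal(out2$pixels[5, 5], 38)   # 50 - mean(10, 12, 14)
  # negatives are preserved, not clamped; empty regions are rejected
  expect_equal(out2$pixels[1, 1], 10 - 12)
  expect_error(subtract_background(ch2, integer(0)), "empty")
  # zero-mean background is the identity
  zch <- calibrated_image(px, 1)
  zidx <- 90:100
  zch$pixels[zidx] <- 0
  expect_equal(subtract_background(zch, zidx)$pixels, zch$pixels)
})

test_that("binning averages complete blocks and rescales the calibration", {
  ch <- calibrated_image(matrix(c(1, 3, 2, 4), 2, 2), 0.1)
  b <- bin_image(ch, 2L)
  expect_equal(dim(b$pixels), c(1L, 1L))
  expect_equal(b$pixels[1, 1], 2.5)
  expect_equal(b$pixel_size_um, 0.2)

  expect_identical(bin_image(ch, 1L), ch)
  # trailing rows/cols are dropped
  ch2 <- calibrated_image(matrix(1:25, 5, 5), 0.1)
  b3 <- bin_image(ch2, 3L)
  expect_equal(dim(b3$pixels), c(1L, 1L))
  expect_equal(b3$pixels[1, 1], mean(ch2$pixels[1:3, 1:3]))
  expect_error(bin_image(ch, 0L), ">= 1")
})

test_that("the uniform-ratio fixture yields exactly 2.0 everywhere", {
  fx <- generate_fret_fixture(true_ratio = 2, noise_sd = 0)
  for (f in c(1L, 2L, 3L)) {
    inp <- fx$input; inp$bin_factor <- f
    s <- fret_summary(inp)
    expect_equal(s$summary$mean_ratio[s$summary$region == "whole_cell"], 2,
                 tolerance = 1e-9)
    expect_equal(s$summary$mean_ratio[s$summary$region == "edge_band"], 2,
                 tolerance = 1e-9)
    expect_true(all(abs(s$map$ratio[s$map$valid_mask] - 2) < 1e-9))
  }
})

test_that("per-pixel ratios and invalid pixels follow the definition", {
  fx <- generate_fret_fixture(true_ratio = 1.5, cfp_level = 20,
                              background = 10, noise_sd = 0)
  map <- fret_ratio_map(fx$input)
  expect_equal(unique(map$ratio[map$valid_mask]), 1.5, tolerance = 1e-12)
  # a zero-CFP pixel inside the cell is invalid and excluded
  inp <- fx$input
  bad <- which(inp$cell_mask)[1]
  inp$cfp$pixels[bad] <- mean(inp$cfp$pixels[inp$background_idx])  # 0 after bg
  map2 <- fret_ratio_map(inp)
  expect_false(map2$valid_mask[bad])
  expect_true(is.na(map2$ratio[bad]))
})

test_that("ratio is invariant under joint channel rescaling", {
  fx <- generate_fret_fixture(true_ratio = 1.3, noise_sd = 1, seed = 4)
  base <- fret_ratio_map(fx$input)
  inp <- fx$input
  inp$cfp <- calibrated_image(inp$cfp$pixels * 3.7, inp$cfp$pixel_size_um)
  inp$yfp <- calibrated_image(inp$yfp$pixels * 3.7, inp$yfp$pixel_size_um)
  scaled <- fret_ratio_map(inp)
  expect_equal(scaled$ratio, base$ratio, tolerance = 1e-9)
})

test_that("edge band has the derived width and partitions the mask", {
  mask <- matrix(FALSE, 120, 120)
  mask[11:110, 11:110] <- TRUE                  # 100 x 100 square cell
  band <- edge_band_mask(mask, band_um = 1.67, pixel_size_um = 0.334)
  # width round(1.67 / 0.334) = 5 px; square-geometry oracle: 100^2 - 90^2
  expect_equal(sum(band), 100^2 - 90^2)
  expect_true(all(mask[band]))                  # subset of the cell
  # band + eroded interior reconstitute the mask exactly
  interior <- mask & !band
  expect_identical(band | interior, mask)
  expect_true(!any(band & interior))

  # a thin cell collapses to the entire cell
  thin <- matrix(FALSE, 40, 40); thin[18:22, 5:35] <- TRUE
  expect_identical(edge_band_mask(thin, 1.67, 0.334), thin)
  # sub-pixel band width is rejected with guidance
  expect_error(edge_band_mask(mask, 1.67, 10), "pixel size")
})

test_that("region means honor validity and report missing when empty", {
  fx <- generate_fret_fixture(true_ratio = 2, noise_sd = 0)
  map <- fret_ratio_map(fx$input)
  region <- matrix(FALSE, 120, 120); region[60:70, 60:70] <- TRUE
  expect_equal(region_mean_ratio(map, region), 2, tolerance = 1e-12)
  outside <- matrix(FALSE, 120, 120); outside[1, 1] <- TRUE
  expect_warning(v <- region_mean_ratio(map, outside), "no valid")
  expect_true(is.na(v))
  # hand-built map: region with valid ratios {1, 2, 3} -> mean 2
  hand <- map
  hand$ratio[region] <- NA_real_
  hand$valid_mask[region] <- FALSE
  pick <- which(region)[1:3]
  hand$ratio[pick] <- c(1, 2, 3); hand$valid_mask[pick] <- TRUE
  expect_equal(region_mean_ratio(hand, region), 2)
})

test_that("compartment-restricted FRET recovers a local ratio difference", {
  rt <- matrix(1, 120, 120)
  comp <- matrix(FALSE, 120, 120); comp[50:60, 50:60] <- TRUE
  rt[comp] <- 1.5
  fx <- generate_fret_fixture(true_ratio = rt, noise_sd = 0)
  map <- fret_ratio_map(fx$input)
  expect_equal(region_mean_ratio(map, comp), 1.5, tolerance = 1e-12)
  whole <- region_mean_ratio(map, map$cell_mask)
  expect_gt(whole, 1); expect_lt(whole, 1.5)
  # weighted-mean oracle by pixel counting
  n_cell <- sum(fx$truth$cell_mask)
  n_comp <- sum(comp & fx$truth$cell_mask)
  expect_equal(whole, (1 * (n_cell - n_comp) + 1.5 * n_comp) / n_cell,
               tolerance = 1e-12)
})

test_that("fret_input validates geometry and background disjointness", {
  fx <- generate_fret_fixture()
  inp <- fx$input
  expect_error(fret_input(inp$cfp, calibrated_image(matrix(1, 5, 5), 0.334),
                          inp$cell_mask, inp$background_idx),
               "share geometry")
  expect_error(fret_input(inp$cfp, inp$yfp, inp$cell_mask,
                          which(inp$cell_mask)[1]), "outside the cell")
  expect_error(fret_input(inp$cfp, inp$yfp, inp$cell_mask, integer(0)),
               "empty")
})
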