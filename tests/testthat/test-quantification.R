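test_that("ROI statistics use the population SD and mean + k*sd", {
  const <- calibrated_image(matrix(5, 10, 10), 0.1)
  s <- roi_statistics(const, k = 1)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$threshold, 5)

  img <- calibrated_image(matrix(c(0, 0, 10, 10), 2, 2), 0.1)
  s2 <- roi_statistics(img, k = 1)
  expect_equal(s2$mean, 5)
  expect_equal(s2$sd, 5)       # population SD, not sample SD
  expect_equal(s2$threshold, 10)

  s0 <- roi_statistics(img, k = 0)
  expect_equal(s0$threshold, s0$mean)
  expect_error(roi_statistics(img, k = -1), "non-negative")
})

test_that("region measurements cover exactly the region pixels", {
  img <- make_disk_image(64L, five_disk_centers(), radius = 5L)
  labs <- segment_compartments(img, segmentation_params(
    gaussian_sigma_px = 0, threshold_method = "fixed", fixed_threshold = 100,
    closing_radius_px = 0L))
  uniform <- calibrated_image(matrix(7, 64, 64), 0.1)
  m <- measure_regions(labs, uniform)
  expect_equal(nrow(m), 5L)
  expect_true(all(m$mean_intensity == 7))
  expect_true(all(m$sd_intensity == 0))
  expect_equal(m$area_px, labs$areas_px)

  # hand-computed mean/sd over a known pixel set
  px <- matrix(0, 64, 64)
  target <- which(labs$label_map == 1L)[1:3]
  px[target] <- c(10, 20, 30)
  vals <- calibrated_image(px, 0.1)
  m1 <- measure_pixel_sets(list(target), vals$pixels)
  expect_equal(m1$mean_intensity, 20)
  expect_equal(m1$sd_intensity, sqrt(200 / 3), tolerance = 1e-12)

  # geometry mismatch rejected
  expect_error(measure_regions(labs, calibrated_image(matrix(1, 32, 32), 0.1)),
               "geometry")
})

test_that("pseudo-compartment measurements use the rasterized pixel sets", {
  set.seed(8)
  protein <- calibrated_image(matrix(runif(100 * 100, 0, 50), 100), 0.1)
  ps <- generate_pseudo_compartments(c(100L, 100L), 0.1,
          pseudo_compartment_params(n = 25L, seed = 14))
  m <- measure_regions(ps, protein)
  expect_equal(nrow(m), 25L)
  i <- 7L
  v <- protein$pixels[ps$pixels[[i]]]
  expect_equal(m$mean_intensity[i], mean(v))
  expect_equal(m$sd_intensity[i], sqrt(mean((v - mean(v))^2)))
  # empty region set -> empty measurement table
  none <- generate_pseudo_compartments(c(100L, 100L), 0.1,
            pseudo_compartment_params(n = 0L))
  expect_equal(nrow(measure_regions(none, protein)), 0L)
})

test_that("positivity calls are strict at the threshold", {
  stats <- structure(list(mean = 100, sd = 20, k = 1, threshold = 120),
                     class = "roi_stats")
  meas <- data.frame(id = 1:3, area_px = 10,
                     mean_intensity = c(121, 120, 119), sd_intensity = 0)
  res <- classify_positive(meas, stats)
  expect_identical(res$calls, c(TRUE, FALSE, FALSE))
  expect_equal(res$percent_positive, 100 / 3)

  # constant ROI: every region mean equals the ROI mean -> all negative
  const <- calibrated_image(matrix(42, 20, 20), 0.1)
  s <- roi_statistics(const, k = 1)
  meas2 <- data.frame(id = 1, area_px = 5, mean_intensity = 42,
                      sd_intensity = 0)
  expect_equal(classify_positive(meas2, s)$n_positive, 0L)

  # k switches the call: mean 130 positive at k=1, negative at k=2
  s1 <- structure(list(mean = 100, sd = 20, k = 1, threshold = 120),
                  class = "roi_stats")
  s2 <- structure(list(mean = 100, sd = 20, k = 2, threshold = 140),
                  class = "roi_stats")
  meas3 <- data.frame(id = 1, area_px = 5, mean_intensity = 130,
                      sd_intensity = 0)
  expect_true(classify_positive(meas3, s1)$calls)
  expect_false(classify_positive(meas3, s2)$calls)

  # no regions: percent positive is missing, not zero
  res0 <- classify_positive(meas[0, ], stats)
  expect_true(is.na(res0$percent_positive))
  expect_equal(res0$n_total, 0L)
})

test_that("rank-sum test reproduces the frozen exact examples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)       # 2/20 enumerated assignments
  expect_equal(r$method, "exact")

  tied <- rank_sum_test(c(1, 2), c(1, 2))
  expect_equal(tied$statistic, 2)    # n1*n2/2 by symmetry

  # U counts (a > b) pairs; here only (3 > 2), so U_a = 1 and U_b = 3
  r2 <- rank_sum_test(c(1, 3), c(2, 4))
  expect_equal(r2$statistic, 1)
  expect_equal(rank_sum_test(c(2, 4), c(1, 3))$statistic, 3)
  expect_equal(r2$statistic + 3, 2 * 2)  # U_a + U_b = n1 * n2
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact p matches exhaustive enumeration for all small sizes", {
  set.seed(77)
  for (n1 in 1:5) for (n2 in 1:5) {
    for (rep in 1:3) {
      pool <- sample(seq_len(50), n1 + n2)   # tie-free by construction
      a <- pool[seq_len(n1)]; b <- pool[-seq_len(n1)]
      got <- rank_sum_test(a, b)
      want <- oracle_rank_sum_exact(a, b)
      expect_equal(got$statistic, want$U)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  }
})

test_that("large-sample p agrees with the tie-corrected normal reference", {
  set.seed(42)
  a <- rnorm(40); b <- rnorm(60, 0.4)
  got <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # with heavy ties
  a2 <- sample(1:4, 30, replace = TRUE); b2 <- sample(2:5, 30, replace = TRUE)
  got2 <- rank_sum_test(a2, b2)
  ref2 <- stats::wilcox.test(a2, b2, exact = FALSE, correct = FALSE)
  expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-10)
  # degenerate all-equal samples: p = 1, U at the midpoint
  deg <- rank_sum_test(rep(3, 8), rep(3, 9))
  expect_equal(deg$statistic, 8 * 9 / 2)
  expect_equal(deg$p_value, 1)
})
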