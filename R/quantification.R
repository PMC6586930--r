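#' ROI-wide intensity statistics and positivity threshold
#'
#' Mean and population standard deviation (divide by N, matching ImageJ
#' measurement semantics) of the protein channel over the whole ROI, and the
#' derived positivity threshold `mean + k * sd`. The published rule uses
#' `k = 1` ("mean + 1 fold SD").
#'
#' @param protein a [calibrated_image()] (the protein channel ROI crop).
#' @param k non-negative threshold multiplier.
#' @return an object of class `roi_stats`: fields `mean`, `sd`, `k`,
#'   `threshold`.
#' @export
roi_statistics <- function(protein, k = 1) {
  stopifnot(inherits(protein, "calibrated_image"))
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop("k must be a single non-negative number", call. = FALSE)
  }
  v <- as.numeric(protein$pixels)
  if (length(v) == 0L) stop("empty ROI", call. = FALSE)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  structure(list(mean = m, sd = s, k = as.numeric(k),
                 threshold = m + k * s),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.4g, sd %.4g, k = %g -> threshold %.4g\n",
              x$mean, x$sd, x$k, x$threshold))
  invisible(x)
}

# Population mean/sd of the protein channel over a list of pixel-index sets.
measure_pixel_sets <- function(pixel_sets, values) {
  n <- length(pixel_sets)
  out <- data.frame(id = seq_len(n), area_px = integer(n),
                    mean_intensity = numeric(n), sd_intensity = numeric(n))
  for (i in seq_len(n)) {
    v <- values[pixel_sets[[i]]]
    out$area_px[i] <- length(v)
    m <- mean(v)
    out$mean_intensity[i] <- m
    out$sd_intensity[i] <- sqrt(mean((v - m)^2))
  }
  out
}

#' Measure protein intensity in real or pseudo compartments
#'
#' Computes area, mean and population standard deviation of the protein
#' channel over exactly the pixels of each region — the quantities the
#' original plugin saves per compartment.
#'
#' @param regions a [segment_compartments()] result or a
#'   [generate_pseudo_compartments()] result sharing the protein channel's
#'   geometry.
#' @param protein a [calibrated_image()].
#' @return data.frame with columns `id`, `area_px`, `mean_intensity`,
#'   `sd_intensity` (one row per region; empty for an empty region set).
#' @export
measure_regions <- function(regions, protein) {
  stopifnot(inherits(protein, "calibrated_image"))
  px <- protein$pixels
  if (inherits(regions, "labeled_compartments")) {
    if (!identical(dim(regions$label_map), dim(px))) {
      stop("regions and protein channel must share geometry", call. = FALSE)
    }
    k <- count_compartments(regions)
    idx <- which(regions$label_map > 0L)
    sets <- split(idx, regions$label_map[idx])
    sets <- sets[as.character(seq_len(k))]
  } else if (inherits(regions, "pseudo_compartments")) {
    if (!identical(as.integer(regions$roi_shape), as.integer(dim(px)))) {
      stop("pseudo-compartments and protein channel must share geometry",
           call. = FALSE)
    }
    sets <- regions$pixels
  } else {
    stop("regions must be labeled_compartments or pseudo_compartments",
         call. = FALSE)
  }
  measure_pixel_sets(sets, px)
}

#' Classify compartments as positive for the protein of interest
#'
#' A region is positive when its mean protein intensity strictly exceeds
#' the threshold `mean + k * sd` of the reference statistics ("above" /
#' "higher than" is read as a strict inequality).
#'
#' @param measurements a [measure_regions()] data.frame.
#' @param stats an [roi_statistics()] result from the same protein channel.
#' @return an object of class `positivity_result`: per-region logical
#'   `calls`, `threshold`, `n_positive`, `n_total` and `percent_positive`
#'   (`NA` — not 0 — when there are no regions to classify).
#' @export
classify_positive <- function(measurements, stats) {
  stopifnot(is.data.frame(measurements), inherits(stats, "roi_stats"))
  calls <- measurements$mean_intensity > stats$threshold
  n_total <- nrow(measurements)
  n_pos <- sum(calls)
  structure(list(calls = calls, threshold = stats$threshold, k = stats$k,
                 n_positive = n_pos, n_total = n_total,
                 percent_positive =
                   if (n_total == 0L) NA_real_ else 100 * n_pos / n_total),
            class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  if (x$n_total == 0L) {
    cat("<positivity_result> no regions to classify (percent positive undefined)\n")
  } else {
    cat(sprintf(
      "<positivity_result> %d / %d positive (%.1f%%) at threshold %.4g (k = %g)\n",
      x$n_positive, x$n_total, x$percent_positive, x$threshold, x$k))
  }
  invisible(x)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Compares two samples (here: per-region mean intensities at real vs.
#' pseudo-compartments). The U statistic counts pairs `(a_i, b_j)` with
#' `a_i > b_j`, ties counting one half (midrank convention). The p-value is
#' exact (null permutation distribution of U) for `n1 + n2 <= 12` without
#' ties, and a normal approximation with tie-corrected variance otherwise.
#'
#' @param a,b non-empty numeric vectors.
#' @return an object of class `rank_sum_test`: `statistic` (U for sample
#'   `a`), `p_value`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1L)
  if (!has_ties && N <= 12L) {
    # exact null distribution of U
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(statistic = U, p_value = min(1, max(p, .Machine$double.xmin)),
                 n1 = n1, n2 = n2, method = method),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s)\nU = %g (n1 = %d, n2 = %d), two-sided p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}
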