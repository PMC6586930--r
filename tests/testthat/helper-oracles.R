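# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms from the package code.

# Stack-based 8-connected flood fill (vs. the package's min-label
# propagation). Returns an integer label matrix.
oracle_flood_fill8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nextlab
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# Canonical representation of a labeling: the set of per-component pixel
# sets, order-independent.
label_partition <- function(lab) {
  idx <- which(lab > 0L)
  sets <- split(idx, lab[idx])
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# Explicit pixel enumeration of a rasterized disk (linear indices into an
# nr x nc matrix): all pixels whose center is within `radius` of the disk
# center.
oracle_disk_pixels <- function(center_row, center_col, radius, nr) {
  px <- integer(0)
  for (dc in -radius:radius) for (dr in -radius:radius) {
    if (dr^2 + dc^2 <= radius^2) {
      px <- c(px, (center_col + dc - 1L) * nr + (center_row + dr))
    }
  }
  sort(px)
}

# Exhaustive-enumeration Mann-Whitney for tie-free samples: U counts pairs
# a_i > b_j; the null distribution enumerates every assignment of the
# pooled ranks to the first sample.
oracle_rank_sum_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  U_obs <- sum(outer(a, b, ">"))
  subsets <- utils::combn(N, n1)
  U_null <- apply(subsets, 2L, function(s) sum(s) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(U_null <= U_obs), mean(U_null >= U_obs))
  list(U = U_obs, p = min(1, p))
}

# A marker image of disjoint hard-edged disks on a flat background.
make_disk_image <- function(size = 64L, centers, radius = 5L,
                            fg = 200, bg = 10, pixel_size_um = 0.1) {
  m <- matrix(bg, size, size)
  for (i in seq_len(nrow(centers))) {
    m[oracle_disk_pixels(centers[i, 1L], centers[i, 2L], radius, size)] <- fg
  }
  calibrated_image(m, pixel_size_um)
}

five_disk_centers <- function() {
  cbind(c(12L, 12L, 32L, 52L, 52L), c(12L, 52L, 32L, 12L, 52L))
}

# Self-colocalization image: the protein channel is the marker channel
# plus additive Gaussian noise at `frac` of the marker foreground.
self_coloc_image <- function(seed, n = 50L, frac = 0.05) {
  fx <- generate_colocalization_fixture(synthetic_params(
    n_compartments = n, fraction_enriched = 0, seed = seed))
  mk <- fx$image$marker$pixels
  protein <- pmax(mk + stats::rnorm(length(mk), 0, frac * 200), 0)
  list(image = two_channel_image(
         fx$image$marker,
         calibrated_image(matrix(protein, nrow(mk), ncol(mk)),
                          fx$image$marker$pixel_size_um)),
       truth = fx$truth)
}
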