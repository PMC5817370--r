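# Shared in-code fixtures.

# A small noiseless phantom, cheap to segment in tests.
quiet_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(noise_sigma_ct = 0, noise_sigma_suv = 0,
                                bias_amplitude = 0, seed = seed, ...))
}

# Random 0/1 mask pair guaranteed nonempty.
random_mask_pair <- function(n = 32, p = 0.3) {
  repeat {
    a <- matrix(as.integer(stats::runif(n * n) < p), n, n)
    b <- matrix(as.integer(stats::runif(n * n) < p), n, n)
    if (sum(a) > 0 && sum(b) > 0) return(list(a = a, b = b))
  }
}

# Brute-force metric oracles (set arithmetic / double loops).
oracle_dice <- function(a, b) {
  inter <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] > 0 && b[i, j] > 0) inter <- inter + 1
  }
  2 * inter / (sum(a > 0) + sum(b > 0)) * 100
}

oracle_fp <- function(a, b) {
  inter <- 0; nb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (b[i, j] > 0) nb <- nb + 1
    if (a[i, j] > 0 && b[i, j] > 0) inter <- inter + 1
  }
  (nb - inter) / sum(a > 0) * 100
}

oracle_hausdorff <- function(pa, pb, spacing = 1) {
  h_ab <- 0
  for (i in seq_len(nrow(pa))) {
    dmin <- Inf
    for (j in seq_len(nrow(pb))) {
      d <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      if (d < dmin) dmin <- d
    }
    if (dmin > h_ab) h_ab <- dmin
  }
  h_ba <- 0
  for (j in seq_len(nrow(pb))) {
    dmin <- Inf
    for (i in seq_len(nrow(pa))) {
      d <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      if (d < dmin) dmin <- d
    }
    if (dmin > h_ba) h_ba <- dmin
  }
  max(h_ab, h_ba) * spacing
}

# Boundary pixels the way the metrics module defines them (4-neighbour).
oracle_boundary <- function(mask) {
  out <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] > 0) {
      nb <- c(
        if (i > 1) mask[i - 1, j] else 0,
        if (i < nr) mask[i + 1, j] else 0,
        if (j > 1) mask[i, j - 1] else 0,
        if (j < nc) mask[i, j + 1] else 0
      )
      if (any(nb == 0)) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Two-phase 64x64 test image with smooth intensity inhomogeneity: a bright
# blob on a dark background, both modulated by a slow gradient.
two_phase_image <- function(n = 64, seed = 42) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  blob <- (rr - n / 2)^2 + (cc - n / 2)^2 <= (n / 5)^2
  img <- matrix(60, n, n)
  img[blob] <- 180
  bias <- 1 + 0.15 * cos(pi * (rr - 1) / (n - 1)) * cos(pi * (cc - 1) / (n - 1))
  img <- img * bias
  set.seed(seed)
  pmin(pmax(img + matrix(rnorm(n * n, 0, 4), n, n), 0), 255)
}

disk_mask <- function(n, center, radius) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  matrix(as.integer((rr - center[1])^2 + (cc - center[2])^2 <= radius^2), n, n)
}
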