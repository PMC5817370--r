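# Naive two-pass summation oracle for Shannon entropy.
oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

test_that("shannon_entropy matches hand values and the summation oracle", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  set.seed(4)
  for (rep in 1:50) {
    x <- rexp(sample(2:20, 1))
    p <- x / sum(x)
    expect_equal(shannon_entropy(p), oracle_entropy(p), tolerance = 1e-12)
  }
})

test_that("invalid probability vectors are rejected", {
  expect_error(shannon_entropy(c(0.5, -0.1, 0.6)),
               class = "invalid_distribution_error")
  expect_error(shannon_entropy(c(0.5, 0.4)),
               class = "invalid_distribution_error")
})

test_that("region entropy of a constant region is log2(n)", {
  for (n in c(1, 4, 9, 100)) {
    expect_equal(suv_region_entropy(rep(3.7, n)), log2(n))
  }
})

test_that("region entropy follows the density-normalize-sum oracle", {
  # symmetric two-level region: all |v - mean| equal, so densities are equal
  expect_equal(suv_region_entropy(c(0, 0, 10, 10)), 2)
  # asymmetric region: skewed densities, entropy strictly below log2(n)
  expect_lt(suv_region_entropy(c(0, 0, 0, 100)), 2)
  # direct oracle on random regions
  set.seed(5)
  for (rep in 1:20) {
    v <- runif(sample(3:30, 1), 0, 10)
    ci <- mean(v); si <- max(sd(v), 1e-3)
    dens <- dnorm(v, ci, si)
    expect_equal(suv_region_entropy(v), oracle_entropy(dens / sum(dens)),
                 tolerance = 1e-10)
  }
  expect_error(suv_region_entropy(numeric(0)), class = "empty_region_error")
})

test_that("region entropy is permutation invariant and bounded by log2(n)", {
  set.seed(6)
  v <- runif(25, 0, 8)
  expect_equal(suv_region_entropy(v), suv_region_entropy(sample(v)))
  for (rep in 1:10) {
    v <- runif(sample(2:40, 1), 0, 8)
    expect_lte(suv_region_entropy(v), log2(length(v)) + 1e-12)
  }
})

test_that("edge guide is small on SUV-homogeneous halves, larger on mixed ones", {
  n <- 21
  suv <- matrix(0.5, n, n)
  phi <- matrix(rep(seq_len(n) - 10.5, each = n), n, n)  # inside = right half
  suv[phi >= 0] <- 8  # homogeneous nodule inside, homogeneous parenchyma out
  g_hom <- edge_guide(suv, phi, c(11, 11), radius_r_px = 5)
  # same geometry but the inside mixes two uptake levels asymmetrically
  # (a balanced 50/50 mix is symmetric about its mean and stays maximal)
  suv_mix <- suv
  suv_mix[phi >= 0] <- rep(c(8, 0.5, 0.5, 0.5), length.out = sum(phi >= 0))
  g_mix <- edge_guide(suv_mix, phi, c(11, 11), radius_r_px = 5)
  expect_gt(g_mix["F1"], g_hom["F1"])
  expect_true(all(g_hom > 0 & g_hom <= 1))
  expect_true(all(g_mix > 0 & g_mix <= 1))
})

test_that("edge guide returns unit weights when one side is empty", {
  suv <- matrix(1, 9, 9)
  phi <- matrix(1, 9, 9)  # everything inside
  expect_warning(g <- edge_guide(suv, phi, c(5, 5), radius_r_px = 3))
  expect_equal(unname(g), c(1, 1))
})

test_that("guide field matches the pointwise oracle at every pixel", {
  set.seed(7)
  suv <- matrix(runif(100, 0, 8), 10, 10)
  phi <- matrix(rep(seq(-4.5, 4.5), each = 10), 10, 10)
  g <- build_guide_field(suv, phi, radius_r_px = 3, band_px = Inf)
  for (i in seq_len(10)) for (j in seq_len(10)) {
    eg <- suppressWarnings(edge_guide(suv, phi, c(i, j), radius_r_px = 3))
    expect_equal(g$F1[i, j], unname(eg["F1"]), tolerance = 1e-10)
    expect_equal(g$F2[i, j], unname(eg["F2"]), tolerance = 1e-10)
  }
  expect_true(all(g$F1 > 0 & g$F1 <= 1))
  expect_true(all(g$F2 > 0 & g$F2 <= 1))
})

test_that("guide field errors when the contour has collapsed", {
  suv <- matrix(1, 8, 8)
  expect_error(build_guide_field(suv, matrix(2, 8, 8)),
               class = "evolution_collapsed_error")
  expect_error(build_guide_field(suv, matrix(-2, 8, 8)),
               class = "evolution_collapsed_error")
})

test_that("outside the band the guide weights default to one", {
  set.seed(8)
  suv <- matrix(runif(900, 0, 8), 30, 30)
  phi <- petctseg:::signed_distance(disk_mask(30, c(15, 15), 6))
  g <- build_guide_field(suv, phi, radius_r_px = 5, band_px = 3)
  far <- abs(phi) > 4
  expect_true(all(g$F1[far] == 1))
  expect_true(all(is.na(g$H_suv_inside[far])))
  near <- abs(phi) <= 3
  expect_true(all(g$F1[near] < 1))
})

test_that("the guide suppresses motion at the nodule boundary more than at the vessel junction", {
  # neighbourhood radius smaller than the nodule so that contour points on
  # the far side of the nodule do not see the vessel at all
  s <- quiet_phantom(nodule_radius_mm = 10)
  phi <- petctseg:::signed_distance(s$truth_mask)
  g <- build_guide_field(s$suv, phi, radius_r_px = 5, band_px = 1)
  band <- is.finite(g$H_suv_inside)
  ctr <- s$spec$nodule_center
  theta <- s$spec$vessel_angle_deg * pi / 180
  rr <- matrix(seq_len(128), 128, 128)
  cc <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  dist_line <- abs(-sin(theta) * (rr - ctr[1]) + cos(theta) * (cc - ctr[2]))
  junction <- band & dist_line <= 2      # contour pixels where the vessel crosses
  away <- band & dist_line > 8           # contour against plain parenchyma
  expect_gt(mean(g$F2[junction]), mean(g$F2[away]))
})
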