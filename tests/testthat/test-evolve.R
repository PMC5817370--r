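test_that("smoothed Heaviside and Dirac satisfy their closed-form identities", {
  for (eps in c(0.5, 1, 2)) {
    expect_equal(heaviside_smooth(0, eps), 0.5)
    expect_equal(heaviside_smooth(eps, eps), 0.75)
    expect_equal(dirac_smooth(0, eps), 1 / (pi * eps))
  }
  expect_equal(dirac_smooth(1, 1), 1 / (2 * pi))
  expect_lt(abs(heaviside_smooth(1e8, 1) - 1), 1e-7)
  expect_lt(abs(heaviside_smooth(-1e8, 1)), 1e-7)
  expect_error(heaviside_smooth(0, 0), class = "parameter_error")
})

test_that("the Dirac function is the Heaviside derivative and integrates to one", {
  x <- seq(-5, 5, by = 0.25)
  h <- 1e-6
  num_deriv <- (heaviside_smooth(x + h, 1) - heaviside_smooth(x - h, 1)) / (2 * h)
  expect_equal(num_deriv, dirac_smooth(x, 1), tolerance = 1e-6)
  q <- integrate(dirac_smooth, -1000, 1000, epsilon = 1)
  expect_lt(abs(q$value - 1), 1e-3)
})

test_that("Gaussian fits reproduce constants and separate a step image", {
  phi <- matrix(rep(seq(-9.5, 9.5), each = 20), 20, 20)
  cfit <- gaussian_fit(matrix(7, 20, 20), phi)
  expect_equal(cfit$f1, matrix(7, 20, 20), tolerance = 1e-10)
  expect_equal(cfit$f2, matrix(7, 20, 20), tolerance = 1e-10)

  img <- matrix(50, 20, 20)
  img[phi >= 0] <- 200
  sfit <- gaussian_fit(img, phi, sigma_g = 1.5)
  # away from the step the fits recover the side values
  expect_equal(sfit$f1[, 18], rep(200, 20), tolerance = 1e-6)
  expect_equal(sfit$f2[, 3], rep(50, 20), tolerance = 1e-6)
  # direct convolution oracle at one pixel
  k <- petctseg:::gaussian_kernel(1.5)
  half <- (nrow(k) - 1) / 2
  i <- 10; j <- 10
  h <- heaviside_smooth(phi)
  num <- den <- 0
  for (a in -half:half) for (b in -half:half) {
    ii <- min(max(i + a, 1), 20); jj <- min(max(j + b, 1), 20)
    w <- k[a + half + 1, b + half + 1]
    num <- num + w * img[ii, jj] * h[ii, jj]
    den <- den + w * h[ii, jj]
  }
  expect_equal(sfit$f1[i, j], num / den, tolerance = 1e-6)
})

test_that("curvature of a circle's signed distance is 1/rho near the contour", {
  circle_sdf <- function(n, rho) {
    c0 <- (n + 1) / 2
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    rho - sqrt((rr - c0)^2 + (cc - c0)^2)  # positive inside
  }
  kmag <- function(rho) {
    n <- 2 * rho + 21
    phi <- circle_sdf(n, rho)
    kap <- curvature(phi)
    mean(abs(kap[abs(phi) <= 1]))
  }
  for (rho in c(10, 15, 20)) {
    expect_lt(abs(kmag(rho) - 1 / rho) / (1 / rho), 0.10)
  }
  # planar level sets are flat
  plane <- outer(seq_len(20), seq_len(20), function(r, c) 0.3 * r + 0.7 * c)
  expect_lt(max(abs(curvature(plane)[3:18, 3:18])), 1e-8)
  # curvature magnitude decreases with radius
  expect_gt(kmag(10), kmag(20))
})

test_that("data terms match a loop-based oracle and gate by channel", {
  set.seed(10)
  n <- 8
  ct <- matrix(runif(n^2, 0, 255), n, n)
  suv <- matrix(runif(n^2, 0, 255), n, n)
  fit <- list(f1_ct = matrix(runif(n^2, 0, 255), n, n),
              f2_ct = matrix(runif(n^2, 0, 255), n, n),
              f1_suv = matrix(runif(n^2, 0, 255), n, n),
              f2_suv = matrix(runif(n^2, 0, 255), n, n))
  guide <- list(F1 = matrix(runif(n^2), n, n), F2 = matrix(runif(n^2), n, n))
  terms <- pointwise_data_terms(ct, suv, fit, guide, Lambda1 = 1, Lambda2 = 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    expect_equal(terms$e1[i, j],
                 guide$F1[i, j] * ((ct[i, j] - fit$f1_ct[i, j])^2 +
                                     (suv[i, j] - fit$f1_suv[i, j])^2))
    expect_equal(terms$e2[i, j],
                 guide$F2[i, j] * ((ct[i, j] - fit$f2_ct[i, j])^2 +
                                     (suv[i, j] - fit$f2_suv[i, j])^2))
  }
  # zero residual when the image equals its fits
  z <- pointwise_data_terms(ct, suv,
                            list(f1_ct = ct, f2_ct = ct, f1_suv = suv,
                                 f2_suv = suv), guide)
  expect_equal(z$e1, matrix(0, n, n))
  expect_equal(z$e2, matrix(0, n, n))
  # Lambda2 = 0 drops the SUV channel entirely
  g1 <- pointwise_data_terms(ct, suv, fit, NULL, Lambda1 = 1, Lambda2 = 0)
  expect_equal(g1$e1, (ct - fit$f1_ct)^2)
})

test_that("total energy matches a brute-force loop oracle", {
  set.seed(11)
  n <- 8
  e1 <- matrix(runif(n^2, 0, 10), n, n)
  e2 <- matrix(runif(n^2, 0, 10), n, n)
  phi <- matrix(rnorm(n^2, 0, 2), n, n)
  en <- total_energy(e1, e2, phi, lambda1 = 1, lambda2 = 1, nu = 2, mu = 3,
                     epsilon = 1)
  cl <- function(i, lo, hi) min(max(i, lo), hi)
  E <- L <- P <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- 0.5 * (1 + 2 / pi * atan(phi[i, j]))
    E <- E + e1[i, j] * h + e2[i, j] * (1 - h)
    gr <- (phi[cl(i + 1, 1, n), j] - phi[cl(i - 1, 1, n), j]) / 2
    gc <- (phi[i, cl(j + 1, 1, n)] - phi[i, cl(j - 1, 1, n)]) / 2
    g <- sqrt(gr^2 + gc^2)
    L <- L + (1 / pi) / (1 + phi[i, j]^2) * g
    P <- P + 0.5 * (g - 1)^2
  }
  expect_equal(en$E_fit, E, tolerance = 1e-10)
  expect_equal(en$L, L, tolerance = 1e-10)
  expect_equal(en$P, P, tolerance = 1e-10)
  expect_equal(en$F, E + 2 * L + 3 * P, tolerance = 1e-10)
})

test_that("a signed distance function has near-zero regularization energy", {
  phi <- petctseg:::signed_distance(disk_mask(41, c(21, 21), 10))
  en <- total_energy(matrix(0, 41, 41), matrix(0, 41, 41), phi)
  expect_lt(en$P / (41 * 41), 0.02)
  expect_equal(en$F, 0.001 * 255^2 * en$L + en$P, tolerance = 1e-10)
})

test_that("the data force points away from the worse-fitting side", {
  n <- 21
  phi <- petctseg:::signed_distance(disk_mask(n, c(11, 11), 5))
  e1 <- matrix(0, n, n); e2 <- matrix(0, n, n)
  e1[9:13, 9:13] <- 50  # inside fits poorly near the centre-left of the contour
  upd <- level_set_step(phi, e1, e2, dt = 0.1, nu = 0, mu = 0)
  # where e1 > e2 and delta > 0, phi must decrease (contour retreats)
  moved <- upd - phi
  expect_true(all(moved[9:13, 9:13] < 0))
  expect_equal(moved[1, 1], 0)
  # balanced data leaves only the distance regularizer
  updb <- level_set_step(phi, e1, e1, dt = 0.1, nu = 0, mu = 1)
  kap <- curvature(phi)
  lap <- petctseg:::laplacian(phi)
  expect_equal(updb, phi + 0.1 * (lap - kap), tolerance = 1e-12)
})

test_that("energy is non-increasing over 100 steps on fixed fields", {
  set.seed(12)
  n <- 41
  phi <- petctseg:::signed_distance(disk_mask(n, c(21, 21), 8))
  e1 <- matrix(runif(n^2, 0, 500), n, n)
  e2 <- matrix(runif(n^2, 0, 500), n, n)
  cfg <- seg_config()
  dt_state <- list(dt = cfg$dt, halvings = 0L)
  en <- total_energy(e1, e2, phi, cfg$lambda1, cfg$lambda2, cfg$nu, cfg$mu,
                     cfg$epsilon)
  f0 <- en$F
  fs <- numeric(100)
  for (k in 1:100) {
    dn <- petctseg:::descend_once(phi, e1, e2, en, dt_state, cfg)
    phi <- dn$phi; dt_state <- dn$dt_state
    en <- total_energy(e1, e2, phi, cfg$lambda1, cfg$lambda2, cfg$nu, cfg$mu,
                       cfg$epsilon)
    fs[k] <- en$F
  }
  expect_true(all(diff(c(f0, fs)) <= 1e-6 * f0))
})

test_that("evolution with K_max = 0 returns the initialization mask", {
  s <- quiet_phantom()
  init <- disk_mask(128, c(64, 64), 7)
  res <- evolve_contour(s$ct, s$suv, init, seg_config(K_max = 0L))
  expect_equal(res$mask, init)
  expect_equal(res$k, 0L)
})

test_that("the level set stays metric near the contour after evolution", {
  s <- quiet_phantom()
  init <- disk_mask(128, c(64, 64), 10)
  res <- evolve_contour(s$ct, s$suv, init, seg_config(K_max = 40L))
  g <- petctseg:::grad_norm(res$phi)
  band <- abs(res$phi) < 5
  expect_gt(mean(g[band]), 0.8)
  expect_lt(mean(g[band]), 1.2)
})

test_that("phantom DSC improves over the first 50 iterations", {
  s <- generate_phantom(phantom_spec())
  roi <- extract_roi(s)
  st <- iterate_threshold(s$ct[roi$roi_mask > 0])
  b <- binarize(s$ct, st$T) * roi$roi_mask
  ic <- select_initial_contour(b)
  d0 <- dice(s$truth_mask, ic$mask)
  res <- evolve_contour(s$ct, s$suv, ic$mask, seg_config(K_max = 50L),
                        roi_mask = roi$roi_mask)
  expect_gt(dice(s$truth_mask, res$mask), d0)
})

test_that("with the SUV channel and guide disabled the model reduces to classic LBF", {
  img <- two_phase_image()
  init <- disk_mask(64, c(32, 32), 16)
  cfg <- seg_config(K_max = 40L, Lambda2 = 0)
  full <- evolve_contour(img, NULL, init, cfg, use_guide = FALSE)
  ref <- lbf_classic(img, init, seg_config(K_max = 40L))
  expect_identical(full$mask, ref$mask)
  expect_identical(full$phi, ref$phi)
  expect_equal(full$energy_trace$F, ref$energy_trace$F)
})

test_that("classic LBF segments a clean two-phase image", {
  img <- two_phase_image()
  init <- disk_mask(64, c(32, 32), 9)
  res <- lbf_classic(img, init, seg_config(K_max = 80L))
  truth <- disk_mask(64, c(32, 32), 64 / 5)
  expect_gt(dice(truth, res$mask), 90)
})
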