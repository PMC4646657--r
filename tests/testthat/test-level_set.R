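test_that("regularised Heaviside and Dirac follow their closed forms", {
  expect_equal(heaviside_eps(0, 1), 0.5)
  expect_equal(dirac_eps(0, 1), 1 / pi)
  expect_equal(dirac_eps(0, 0.25), 1 / (pi * 0.25))
  x <- matrix(seq(-5, 5, length.out = 12), 3, 4)
  for (eps in c(0.1, 1, 2.5)) {
    expect_equal(heaviside_eps(x, eps) + heaviside_eps(-x, eps),
                 matrix(1, 3, 4), tolerance = 1e-14)
    H <- heaviside_eps(x, eps)
    expect_true(all(H > 0 & H < 1))
    expect_true(all(dirac_eps(x, eps) > 0))
  }
  expect_error(heaviside_eps(x, 0), class = "mgdf_validation_error")
  expect_error(dirac_eps(x, -1), class = "mgdf_validation_error")
})

test_that("the Dirac approximation integrates to one", {
  for (eps in c(0.1, 1, 3)) {
    q <- stats::integrate(function(t) dirac_eps(t, eps), -Inf, Inf,
                          rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-5)
  }
})

test_that("binary-step initialisation rasterises seed disks exactly", {
  phi <- initialize_level_set(c(20, 20),
                              list(list(center = c(9.5, 9.5), radius = 5)),
                              c0 = 2)
  expect_setequal(unique(as.vector(phi)), c(-2, 2))
  rr <- matrix(0:19, 20, 20); cc <- t(rr)
  inside <- (rr - 9.5)^2 + (cc - 9.5)^2 <= 25
  expect_identical(phi == -2, inside)
  # zero-radius disk has an empty interior
  phi0 <- initialize_level_set(c(10, 10),
                               list(list(center = c(5, 5), radius = 0)), 2)
  expect_true(all(phi0 == 2))
  # two disjoint disks: interior count is the sum of the rasterised areas
  d1 <- list(center = c(5, 5), radius = 3)
  d2 <- list(center = c(20, 22), radius = 4)
  phi2 <- initialize_level_set(c(28, 28), list(d1, d2), 2)
  count_disk <- function(d, n = 28) {
    g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
    sum((g$r - d$center[1])^2 + (g$c - d$center[2])^2 <= d$radius^2)
  }
  expect_equal(sum(phi2 < 0), count_disk(d1) + count_disk(d2))
  expect_error(initialize_level_set(c(10, 10),
                                    list(list(center = c(20, 5), radius = 2))),
               class = "mgdf_validation_error")
})

test_that("curvature matches its analytic values", {
  n <- 41
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  plane <- 0.3 * rr + 0.7 * cc + 2
  k <- curvature(plane)
  expect_lt(max(abs(k[3:(n - 2), 3:(n - 2)])), 1e-10)
  cone <- sqrt((rr - 20)^2 + (cc - 20)^2)
  k <- curvature(cone)
  r <- cone
  sel <- r >= 5 & r <= 15
  expect_equal(k[sel], 1 / r[sel], tolerance = 0.15)
  expect_equal(curvature(-cone), -k, tolerance = 1e-12)
})

test_that("distance regularisation is stationary on signed distance functions", {
  n <- 41
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  cone <- sqrt((rr - 20)^2 + (cc - 20)^2)
  dr <- distance_regularization(cone)
  interior <- cone >= 5 & cone <= 15
  expect_lt(max(abs(dr[interior])), 0.05)
  expect_equal(distance_regularization(matrix(3, 9, 9)), matrix(0, 9, 9))
  # |grad phi| = 2: iterating the update restores the unit slope
  phi <- 2 * cone
  grad_mag <- function(p) {
    gr <- (p[c(2:nrow(p), nrow(p)), ] - p[c(1, 1:(nrow(p) - 1)), ]) / 2
    gc <- (p[, c(2:ncol(p), ncol(p))] - p[, c(1, 1:(ncol(p) - 1))]) / 2
    mean(sqrt(gr^2 + gc^2)[10:30, 10:30])
  }
  s0 <- grad_mag(phi)
  half <- 0
  for (i in 1:100) {
    phi <- phi + 0.2 * distance_regularization(phi)
    if (i == 50) half <- grad_mag(phi)
  }
  s1 <- grad_mag(phi)
  expect_lt(half, s0)                      # steadily relaxing ...
  expect_lt(s1, half)
  expect_lt(abs(s1 - 1), 0.6 * abs(s0 - 1))  # ... toward unit slope
  expect_gt(s1, 1)
})

test_that("the gamma-neighbourhood force has the documented shape", {
  phi <- matrix(seq(-20, 20, length.out = 25), 5, 5)
  expect_equal(gamma_force(phi, 3, 2, 0), matrix(0, 5, 5))
  # kappa = 1: magnitude tends to eta/gamma near the contour
  expect_equal(abs(gamma_force(matrix(1e-8, 1, 1), 3, 1, 1)[1, 1]),
               1 / 3, tolerance = 1e-6)
  expect_equal(abs(gamma_force(matrix(-1e-8, 1, 1), 3, 1, 1)[1, 1]),
               1 / 3, tolerance = 1e-6)
  # far field decays
  expect_lt(max(abs(gamma_force(matrix(c(-500, 500), 1, 2), 3, 2, 1))), 1e-4)
  # drives |phi| away from zero on both sides (descent on the penalty)
  g <- gamma_force(phi, 3, 2, 1)
  expect_true(all(g[phi > 0.1] > 0))
  expect_true(all(g[phi < -0.1] < 0))
  expect_error(gamma_force(phi, -1, 2, 1), class = "mgdf_validation_error")
  expect_error(gamma_force(phi, 3, 0.5, 1), class = "mgdf_validation_error")
})

test_that("mask extraction is the strict interior indicator", {
  phi <- matrix(c(-1, 0, 2, -0.5), 2, 2)
  expect_equal(extract_mask(phi), (phi < 0) * 1)
  expect_equal(extract_mask(matrix(2, 3, 3)), matrix(0, 3, 3))
  set.seed(8)
  phi2 <- matrix(rnorm(100) + 0.01, 10, 10)     # no exact zeros
  expect_equal(extract_mask(-phi2), 1 - extract_mask(phi2))
  expect_error(extract_mask(matrix(c(1, NA, 1, 1), 2, 2)),
               class = "mgdf_validation_error")
})

test_that("a zero net force leaves the level set stationary", {
  img <- matrix(120, 32, 32)
  cfg <- mgdf_config(upsilon = 0, mu = 0, eta = 0, lambda1_i = 1,
                     lambda2_i = 1, lambda1_v = 0, lambda2_v = 0,
                     max_iters = 1, init_mode = "disks")
  res <- evolve(img, NULL, cfg)
  expect_equal(res$phi, initialize_level_set(c(32, 32), NULL, cfg$c0))
})

test_that("evolution is deterministic and records the energy history", {
  ph <- disk_fixture(noise_std = 3)
  v <- enhance(ph$image, mgdf_config(n_orientations = 4))
  cfg <- fast_config(n_orientations = 4)
  r1 <- evolve(ph$image, v, cfg)
  r2 <- evolve(ph$image, v, cfg)
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$mask, r2$mask)
  expect_equal(nrow(r1$energy), r1$iterations + 1)
  expect_equal(r1$energy$iteration, 0:r1$iterations)
  expect_identical(r1$mask, extract_mask(r1$phi))
})

test_that("the default evolution segments a noisy two-phase disk", {
  ph <- disk_fixture(noise_std = 3)
  v <- enhance(ph$image)
  res <- evolve(ph$image, v, mgdf_config(max_iters = 300),
                seeds = list(list(center = c(31.5, 31.5), radius = 16)))
  expect_gte(dice_score(res$mask, ph$truth), 0.95)
})

test_that("vesselness-guided initialisation thresholds and unions as documented", {
  V <- matrix(c(-0.9, 0.2, 0.6, 0.95), 2, 2)
  expect_equal(vesselness_init(V), matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(vesselness_init(V, 0.1), matrix(c(0, 1, 1, 1), 2, 2))
  expect_error(vesselness_init(V, 1.5), class = "mgdf_validation_error")
})
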