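test_that("the statistics window follows the truncation rule and sums to 1", {
  w <- make_window_kernel(3)
  expect_equal(w$tau, 7L)
  expect_identical(dim(w$weights), c(15L, 15L))
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  w2 <- make_window_kernel(0.5)
  expect_equal(w2$tau, 1L)
  expect_identical(dim(w2$weights), c(3L, 3L))
  expect_equal(which.max(w2$weights), 5L)     # centre weight dominates
  for (s in c(0.7, 1.9, 2.5, 4)) {
    wk <- make_window_kernel(s)
    expect_equal(sum(wk$weights), 1, tolerance = 1e-12)
    expect_true(wk$tau %% 2 == 1 && wk$tau >= 2 * s)
  }
  expect_error(make_window_kernel(0), class = "mgdf_validation_error")
})

test_that("local means and stds recover a two-phase image under the true partition", {
  ph <- disk_fixture(noise_std = 0)
  phi <- truth_phi(ph$truth)
  w <- make_window_kernel(3)
  st <- update_local_stats(ph$image, NULL, phi, w, epsilon = 1e-3)
  r <- sqrt((row(phi) - 1 - 31.5)^2 + (col(phi) - 1 - 31.5)^2)
  deep_in <- r < 15 - (w$tau + 1)
  deep_out <- r > 15 + (w$tau + 1)
  expect_equal(max(abs(st$u1I[deep_in] - 100)) / 100, 0, tolerance = 1e-3)
  expect_equal(max(abs(st$u2I[deep_out] - 20)) / 20, 0, tolerance = 1e-3)
  # zero within-region variance clamps to (near) the floor; the residual
  # above it comes from the regularised Heaviside tails
  expect_lt(max(st$s1I[deep_in]), 0.05)
  expect_lt(max(st$s2I[deep_out]), 0.05)
  expect_gte(min(st$s1I), 1e-2)
})

test_that("local stds recover the noise level inside each region", {
  ph <- disk_fixture(noise_std = 5, seed = 11)
  phi <- truth_phi(ph$truth)
  w <- make_window_kernel(3)
  st <- update_local_stats(ph$image, NULL, phi, w, epsilon = 1e-3)
  r <- sqrt((row(phi) - 1 - 31.5)^2 + (col(phi) - 1 - 31.5)^2)
  deep_in <- r < 15 - (w$tau + 1)
  expect_equal(mean(st$s1I[deep_in]), 5, tolerance = 0.1)
})

test_that("the data force vanishes under perfectly symmetric statistics", {
  n <- 20
  I <- matrix(runif(n * n, 0, 255), n, n)
  w <- make_window_kernel(2)
  u <- matrix(100, n, n); s <- matrix(7, n, n)
  stats <- structure(list(u1I = u, u2I = u, s1I = s, s2I = s),
                     class = "mgdf_local_stats")
  f <- data_force(I, NULL, stats, w,
                  list(l1i = 1.3, l2i = 1.3, l1v = 0, l2v = 0))
  expect_equal(max(abs(f)), 0, tolerance = 1e-10)
})

test_that("the data force restores the correct partition on a two-phase image", {
  ph <- disk_fixture(noise_std = 3)
  r <- sqrt((row(ph$truth) - 1 - 31.5)^2 + (col(ph$truth) - 1 - 31.5)^2)
  phi <- r - 15                       # signed distance to the true boundary
  w <- make_window_kernel(3)
  st <- update_local_stats(ph$image, NULL, phi, w, epsilon = 0.1)
  f <- data_force(ph$image, NULL, st, w,
                  list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0))
  band_out <- r > 15.5 & r < 18
  band_in <- r < 14.5 & r > 12
  expect_gt(mean(f[band_out]), 0)     # pushes phi positive outside
  expect_lt(mean(f[band_in]), 0)      # pushes phi negative inside
})

test_that("nulling the vesselness weights reproduces the single-feature force exactly", {
  ph <- disk_fixture(noise_std = 3)
  phi <- truth_phi(ph$truth)
  set.seed(4)
  V <- matrix(runif(64 * 64, -0.9, 0.9), 64, 64)
  w <- make_window_kernel(3)
  st2 <- update_local_stats(ph$image, V, phi, w, epsilon = 0.1)
  st1 <- update_local_stats(ph$image, NULL, phi, w, epsilon = 0.1)
  f2 <- data_force(ph$image, V, st2, w,
                   list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0))
  f1 <- data_force(ph$image, NULL, st1, w,
                   list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0))
  expect_identical(f2, f1)
})

test_that("energy components behave at their analytic limits", {
  ph <- disk_fixture(noise_std = 0)
  cfg <- mgdf_config()
  w <- make_window_kernel(cfg$sigma)
  lam <- list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0)
  # gamma term: ~0 deep in background, ~eta * npix at phi == 0
  phi_deep <- matrix(1000, 64, 64)
  st <- update_local_stats(ph$image, NULL, phi_deep, w, cfg$epsilon)
  en <- total_energy(ph$image, NULL, phi_deep, st, w, lam, cfg)
  expect_lt(en$gamma_term, 1e-3 * length(phi_deep))
  phi_zero <- matrix(0, 64, 64)
  st0 <- update_local_stats(ph$image, NULL, phi_zero, w, cfg$epsilon)
  en0 <- total_energy(ph$image, NULL, phi_zero, st0, w, lam, cfg)
  expect_equal(en0$gamma_term, cfg$eta * length(phi_zero))
  # distance term: near zero for a unit ramp, clearly positive when scaled
  ramp <- matrix(rep(seq_len(64), each = 64) - 32, 64, 64)
  str_ <- update_local_stats(ph$image, NULL, ramp, w, cfg$epsilon)
  en_r <- total_energy(ph$image, NULL, ramp, str_, w, lam, cfg)
  en_r2 <- total_energy(ph$image, NULL, 2 * ramp, str_, w, lam, cfg)
  expect_lt(en_r$distance_term, 0.05 * en_r2$distance_term)
  expect_gte(en_r$length_term, 0)
  expect_equal(en_r$total,
               en_r$data_intensity + en_r$data_vesselness + en_r$length_term +
                 en_r$distance_term + en_r$gamma_term)
})

test_that("the energy of the correct partition is lower than its inversion", {
  # with the default asymmetric weights (lambda1 > lambda2) the inversion
  # is strictly worse; at equal weights the data term is label-symmetric
  ph <- disk_fixture(noise_std = 3)
  cfg <- mgdf_config()
  w <- make_window_kernel(cfg$sigma)
  lam <- list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0)
  phi <- truth_phi(ph$truth)
  st <- update_local_stats(ph$image, NULL, phi, w, cfg$epsilon)
  e_good <- total_energy(ph$image, NULL, phi, st, w, lam, cfg)$data_intensity
  sti <- update_local_stats(ph$image, NULL, -phi, w, cfg$epsilon)
  e_bad <- total_energy(ph$image, NULL, -phi, sti, w, lam, cfg)$data_intensity
  expect_lt(e_good, e_bad)
})

test_that("statistics and forces are shift-covariant away from the border", {
  set.seed(9)
  n <- 40; dr <- 3; dc <- 5
  I <- matrix(runif(n * n, 0, 255), n, n)
  phi <- matrix(runif(n * n, -3, 3), n, n)
  w <- make_window_kernel(2)
  shift <- function(m) {
    out <- matrix(0, n, n)
    out[(1 + dr):n, (1 + dc):n] <- m[1:(n - dr), 1:(n - dc)]
    out
  }
  st <- update_local_stats(I, NULL, phi, w, epsilon = 0.5)
  f <- data_force(I, NULL, st, w, list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0))
  sts <- update_local_stats(shift(I), NULL, shift(phi), w, epsilon = 0.5)
  fs <- data_force(shift(I), NULL, sts, w,
                   list(l1i = 1.05, l2i = 1, l1v = 0, l2v = 0))
  margin <- 2 * w$tau + 1
  core <- (margin + dr):(n - margin)
  corec <- (margin + dc):(n - margin)
  expect_equal(fs[core + 0, corec], shift(f)[core, corec], tolerance = 1e-9)
})

test_that("mismatched shapes are rejected", {
  w <- make_window_kernel(2)
  expect_error(update_local_stats(matrix(0, 8, 8), NULL, matrix(0, 7, 8), w),
               class = "mgdf_validation_error")
  expect_error(update_local_stats(matrix(0, 8, 8), matrix(0, 8, 7),
                                  matrix(0, 8, 8), w),
               class = "mgdf_validation_error")
})
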