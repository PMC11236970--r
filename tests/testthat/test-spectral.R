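test_that("single-mode spectra and Parseval identity are exact", {
  th <- theta_grid()
  N <- length(th)
  u <- 0.7 * cos(3 * th)
  sp <- deformation_power_spectrum(u)
  expect_equal(sp$power[3], 0.7^2 * N / 2, tolerance = 1e-10)
  expect_lt(sum(sp$power[-3]), 1e-20)
  # Parseval: sum of one-sided power = N * variance for zero-mean u
  u2 <- 0.5 * cos(2 * th) + 0.2 * sin(7 * th) + 0.1 * cos(11 * th)
  sp2 <- deformation_power_spectrum(u2)
  expect_equal(sum(sp2$power), N * mean(u2^2), tolerance = 1e-10)
  expect_error(
    deformation_power_spectrum(u, theta = cumsum(stats::runif(N))),
    "not uniform"
  )
})

test_that("scaling exponent fits recover exact power laws", {
  q <- 1:40
  expect_equal(fit_scaling_exponent(list(q = q, power = q^-4)), 4,
               tolerance = 1e-10)
  expect_equal(fit_scaling_exponent(list(q = q, power = q^-2)), 2,
               tolerance = 1e-10)
  expect_warning(
    a <- fit_scaling_exponent(list(q = q, power = c(q[1:39]^-4, 0))),
    "zero-power"
  )
  expect_equal(a, 4, tolerance = 1e-10)
})

test_that("sampled ensembles land in their scaling regimes", {
  ser <- sample_contour_series(20, kappa = 1, gamma = 0, n_modes = 24,
                               n_frames = 120, seed = 5)
  u <- do.call(rbind, lapply(ser$contours, function(ct) {
    radial_decomposition(ct)$u_um
  }))
  a_k <- fit_scaling_exponent(deformation_power_spectrum(u),
                              q_range = c(2, 24))
  expect_gt(a_k, 3.5); expect_lt(a_k, 4.5)
  serg <- sample_contour_series(20, kappa = 0, gamma = 1, n_modes = 24,
                                n_frames = 120, seed = 6)
  ug <- do.call(rbind, lapply(serg$contours, function(ct) {
    radial_decomposition(ct)$u_um
  }))
  a_g <- fit_scaling_exponent(deformation_power_spectrum(ug),
                              q_range = c(2, 24))
  expect_gt(a_g, 1.8); expect_lt(a_g, 2.6)
})

test_that("Helfrich fit pins absent terms and finds the crossover", {
  # pure bending data: gamma pinned at its zero bound
  ser <- sample_contour_series(20, kappa = 1, gamma = 0, n_modes = 24,
                               n_frames = 400, seed = 7)
  u <- do.call(rbind, lapply(ser$contours, function(ct) {
    radial_decomposition(ct)$u_um
  }))
  fit <- fit_fluctuation_model(deformation_power_spectrum(u), q_max = 24)
  expect_equal(fit$degenerate, "kappa_only")
  expect_equal(fit$gamma_fit, 0, tolerance = 1e-8)
  # expected coefficient: power(q) = N sigma_q^2 / 2 = 1/(kappa_eff q^4)
  C <- 2 * 0.4^2 / sum(1 / (2:24)^4)
  expect_lt(abs(fit$kappa_fit / (2 / (360 * C)) - 1), 0.15)
  # crossover at q = 3 (terms equal) recovered within one mode
  q <- 2:24
  fit2 <- fit_fluctuation_model(list(q = q, power = 1 / (q^4 + 9 * q^2)))
  expect_lt(abs(fit2$crossover_q - 3), 1)
  # scale invariance: c * power leaves the kappa/gamma ratio unchanged
  fit3 <- fit_fluctuation_model(list(q = q,
                                     power = 10 / (q^4 + 9 * q^2)))
  expect_equal(fit3$gamma_fit / fit3$kappa_fit,
               fit2$gamma_fit / fit2$kappa_fit, tolerance = 1e-3)
})

test_that("autocorrelation zero crossings match cosine closed forms", {
  th <- theta_grid()
  expect_equal(angular_autocorrelation_size(cos(2 * th))$theta_c_deg, 45,
               tolerance = 1e-6)
  for (m in c(3, 5, 9)) {
    expect_equal(angular_autocorrelation_size(cos(m * th))$theta_c_deg,
                 90 / m, tolerance = 1e-6)
  }
  # theta_c decreases with the mode number (monotone on single modes)
  tc <- vapply(2:10, function(m) {
    angular_autocorrelation_size(cos(m * th))$theta_c_deg
  }, numeric(1))
  expect_true(all(diff(tc) < 0))
  # ACF symmetry: circular ACF computed forward equals the reversed-u ACF
  u <- 0.4 * cos(2 * th) + 0.2 * sin(5 * th)
  a1 <- angular_autocorrelation_size(u)$acf
  a2 <- angular_autocorrelation_size(rev(u))$acf
  expect_equal(a1, a2, tolerance = 1e-12)
  # all-positive ACF frames are skipped; all skipped is an error
  expect_error(angular_autocorrelation_size(rep(1, 360) + 0 * th), "zero")
})

test_that("multi-frame theta_c takes the minimum and its frame", {
  th <- theta_grid()
  u <- rbind(cos(2 * th), cos(6 * th), cos(4 * th))
  ds <- angular_autocorrelation_size(u)
  expect_equal(ds$theta_c_deg, 15, tolerance = 1e-6)
  expect_equal(ds$t_prime, 2L)
  expect_equal(ds$first_zero_deg, c(45, 15, 22.5), tolerance = 1e-6)
  expect_equal(ds$acf[, 1], rep(1, 3))
})

test_that("coarse-grid zero crossing matches a 10x refined oracle", {
  mix <- function(th) {
    0.5 * cos(2 * th) + 0.3 * cos(5 * (th + 0.4)) + 0.2 * cos(7 * th)
  }
  coarse <- angular_autocorrelation_size(mix(theta_grid(360)))
  dense <- angular_autocorrelation_size(mix(theta_grid(3600)))
  expect_lt(abs(coarse$theta_c_deg - dense$theta_c_deg), 0.5)
})

test_that("Pratt curvature matches closed forms", {
  cv <- local_curvature(circle_contour(R = 20))
  expect_equal(cv$curvature_per_um, rep(0.05, 360), tolerance = 1e-6)
  expect_equal(cv$total_turning, 2 * pi, tolerance = 0.01 * 2 * pi)
  # straight open segment: zero curvature, collinear points flagged
  seg <- list(x = seq(0, 10, length.out = 50), y = rep(2, 50))
  cvs <- local_curvature(seg, separation = 3, closed = FALSE)
  mid <- 10:40
  expect_equal(cvs$curvature_per_um[mid], rep(0, length(mid)))
  expect_true(all(cvs$flagged[mid]))
  # polar two-mode contour against the closed-form polar curvature
  R <- 20; eps <- 0.05
  ct <- mode_contour(R = R, eps = eps, m = 2)
  cv2 <- local_curvature(ct, separation = 5)
  th_v <- atan2(ct$y - ct$center["y"], ct$x - ct$center["x"])
  r <- R * (1 + eps * cos(2 * th_v))
  rp <- -2 * R * eps * sin(2 * th_v)
  rpp <- -4 * R * eps * cos(2 * th_v)
  k_true <- polar_curvature_oracle(r, rp, rpp)
  expect_lt(max(abs(cv2$curvature_per_um / k_true - 1)), 0.02)
})

test_that("total turning is 2 pi for generated simple contours", {
  for (i in 1:10) {
    ser <- sample_contour_series(18, kappa = 1, gamma = 2, n_modes = 16,
                                 u_rms_um = 0.5, n_frames = 1, seed = 60 + i)
    cv <- local_curvature(ser$contours[[1]], separation = 5)
    expect_equal(cv$total_turning, 2 * pi, tolerance = 0.01 * 2 * pi)
  }
})
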