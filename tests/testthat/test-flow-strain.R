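piv_cascade <- list(c(64, 128), c(32, 64))   # scaled-down default cascade

test_that("PIV recovers rigid shifts to sub-pixel accuracy", {
  for (shift_px in c(2, 5, 10)) {
    sp <- make_speckle_pair(
      list(type = "translation", v_um_s = c(shift_px * 0.0938 / 6, 0)),
      n_particles = 2500, dt_s = 6, image_shape = c(256, 256), seed = shift_px
    )
    pf <- piv_displacement(sp$frame_a, sp$frame_b, piv_cascade,
                           pixel_size_um = 0.0938, dt_s = 6)
    expect_gt(mean(pf$valid), 0.9)
    err <- sqrt(mean((pf$u_px[pf$valid] - shift_px)^2 +
                       pf$v_px[pf$valid]^2))
    expect_lt(err, 0.2)
  }
})

test_that("identical frames give a zero field; flat frames give no vectors", {
  sp <- make_speckle_pair(list(type = "translation", v_um_s = c(0, 0)),
                          n_particles = 2000, seed = 7)
  pf <- piv_displacement(sp$frame_a, sp$frame_a, piv_cascade)
  expect_lt(max(abs(c(pf$u_px[pf$valid], pf$v_px[pf$valid]))), 0.1)
  flat <- matrix(1, 256, 256)
  pf0 <- piv_displacement(flat, flat, piv_cascade)
  # featureless windows are invalid, not zero
  expect_false(any(pf0$valid))
  expect_true(all(is.na(pf0$u_px)))
})

test_that("window cascade preconditions are enforced", {
  img <- matrix(stats::runif(64^2), 64, 64)
  expect_error(piv_displacement(img, img, list(c(32, 64), c(32, 64))),
               "strictly decreasing")
  expect_error(piv_displacement(img, img, list(c(32, 16))),
               "exceed")
})

test_that("PIV recovers a radial contraction field within 5% RMS", {
  # volume-contraction configuration: 48 px final interrogation window,
  # dense speckle (~0.09 particles/px^2)
  k <- 0.002
  sp <- make_speckle_pair(
    list(type = "radial_contraction", k_per_s = k, center_um = c(12, 12)),
    n_particles = 6000, dt_s = 6, image_shape = c(256, 256), seed = 4
  )
  pf <- piv_displacement(sp$frame_a, sp$frame_b, list(c(64, 128), c(48, 96)),
                         pixel_size_um = 0.0938, dt_s = 6)
  G <- expand.grid(y = pf$y_um, x = pf$x_um)
  tu <- -k * (G$x - 12) * 6
  tv <- -k * (G$y - 12) * 6
  ok <- as.vector(pf$valid)
  err <- sqrt(mean(((as.vector(pf$u_um) - tu)^2 +
                      (as.vector(pf$v_um) - tv)^2)[ok]))
  expect_lt(err / sqrt(mean(tu^2 + tv^2)), 0.05)
})

test_that("discrete divergence is second-order accurate", {
  ufun <- function(x, y) sin(x / 4) * cos(y / 5)
  vfun <- function(x, y) cos(x / 6) * sin(y / 3)
  divfun <- function(x, y) cos(x / 4) * cos(y / 5) / 4 +
    cos(x / 6) * cos(y / 3) / 3
  err_at <- function(d) {
    g <- seq(0, 24, by = d)
    f <- analytic_field(ufun, vfun, g, g)
    dv <- divergence_field(f)
    G <- expand.grid(y = g, x = g)
    tr <- matrix(divfun(G$x, G$y), length(g), length(g))
    max(abs(dv$div - tr), na.rm = TRUE)
  }
  e1 <- err_at(1); e2 <- err_at(0.5)
  expect_gt(e1 / e2, 3.3)   # halving the spacing cuts the error ~4x
})

test_that("compressive strain integrates only negative divergence", {
  g <- seq(0, 24, by = 1)
  mask <- matrix(TRUE, length(g), length(g))
  # pure translation: divergence-free, epsilon stays 0
  ft <- analytic_field(function(x, y) 3 + 0 * x, function(x, y) -2 + 0 * x,
                       g, g)
  st <- cumulative_compressive_strain(list(ft, ft), mask, dt_s = 6)
  expect_equal(st$epsilon, c(0, 0, 0), tolerance = 1e-12)
  # uniform contraction u_r = -k r: per-step strain 2 k dt, exactly
  k <- 0.001; dt <- 6
  fr <- analytic_field(function(x, y) -k * dt * (x - 12),
                       function(x, y) -k * dt * (y - 12), g, g)
  sr <- cumulative_compressive_strain(list(fr, fr, fr), mask, dt)
  expect_equal(diff(sr$epsilon), rep(2 * k * dt, 3), tolerance = 1e-10)
  expect_equal(sr$rate_per_s[1:3], rep(2 * k, 3), tolerance = 1e-10)
  # epsilon(0) = 0 and monotone non-decreasing
  expect_equal(sr$epsilon[1], 0)
  expect_true(all(diff(sr$epsilon) >= 0))
  # uniform expansion clips to zero rather than going negative
  fe <- analytic_field(function(x, y) k * dt * (x - 12),
                       function(x, y) k * dt * (y - 12), g, g)
  se <- cumulative_compressive_strain(list(fe), mask, dt)
  expect_equal(se$epsilon[2], 0, tolerance = 1e-12)
})

test_that("strain is monotone in the prescribed contraction rate", {
  g <- seq(0, 24, by = 1)
  mask <- matrix(TRUE, length(g), length(g))
  eps120 <- vapply(c(0.0005, 0.001, 0.002), function(k) {
    f <- analytic_field(function(x, y) -k * 6 * (x - 12),
                        function(x, y) -k * 6 * (y - 12), g, g)
    st <- cumulative_compressive_strain(rep(list(f), 20), mask, 6)
    st$epsilon[21]   # epsilon at t = 120 s
  }, numeric(1))
  expect_true(all(diff(eps120) > 0))
})

test_that("strain is exactly invariant under 90-degree scene rotation", {
  g <- seq(0, 20, by = 1)
  f <- analytic_field(function(x, y) -0.01 * (x - 10) + 0.003 * y,
                      function(x, y) -0.008 * (y - 10), g, g)
  mask <- matrix(TRUE, length(g), length(g))
  s0 <- cumulative_compressive_strain(list(f), mask, 6)$epsilon[2]
  # rotate the vector field by +90 degrees: point (x, y) -> (L - y, x),
  # vector (u, v) -> (-v, u); on matrices [row = y, col = x] this is
  # m'[a, b] = m[n + 1 - b, a]
  rot <- function(m) t(m[rev(seq_len(nrow(m))), ])
  f90 <- f
  f90$u_um <- rot(-f$v_um); f90$v_um <- rot(f$u_um)
  f90$u_px <- f90$u_um; f90$v_px <- f90$v_um
  f90$valid <- rot(f$valid); f90$quality <- rot(f$quality)
  s90 <- cumulative_compressive_strain(list(f90), mask, 6)$epsilon[2]
  expect_equal(s90, s0, tolerance = 1e-12)
})

test_that("grid and mask degeneracies raise errors", {
  g <- seq(0, 24, by = 1)
  f <- analytic_field(function(x, y) 0 * x, function(x, y) 0 * x, g, g)
  expect_error(
    cumulative_compressive_strain(list(f),
                                  matrix(FALSE, length(g), length(g)), 6),
    "empty"
  )
  g2 <- c(0, 12, 24)
  f2 <- analytic_field(function(x, y) 0 * x, function(x, y) 0 * x, g2, g2)
  mask2 <- matrix(c(TRUE, rep(FALSE, 8)), 3, 3)
  expect_error(cumulative_compressive_strain(list(f2), mask2, 6), "coarse")
})

test_that("cortical flow speed recovers a prescribed tangential flow", {
  R <- 10; dt <- 6
  ct <- circle_contour(R = R, center = c(12, 12))
  band <- 2
  # rotation whose speed equals 13.3 um/min at the band centre radius
  v_target <- 13.3
  om <- (v_target / 60) / (R - band / 2)
  sw <- make_speckle_pair(
    list(type = "swirl", omega_per_s = om, center_um = c(12, 12)),
    n_particles = 4000, dt_s = dt, image_shape = c(256, 256), seed = 6
  )
  pf <- piv_displacement(sw$frame_a, sw$frame_b, piv_cascade,
                         pixel_size_um = 0.0938, dt_s = dt)
  fs <- cortical_flow_speed(list(pf), ct, band_width_um = band)
  expect_equal(fs$speed_um_per_min, v_target, tolerance = 1)
  expect_gt(fs$tangential_um_per_min, 0.9 * v_target)
  # static scene: zero speed
  pf0 <- piv_displacement(sw$frame_a, sw$frame_a, piv_cascade,
                          pixel_size_um = 0.0938, dt_s = dt)
  fs0 <- cortical_flow_speed(list(pf0), ct, band_width_um = band)
  expect_lt(fs0$speed_um_per_min, 0.5)
  # pure radial flow: tangential component near zero
  spr <- make_speckle_pair(
    list(type = "radial_contraction", k_per_s = 0.002, center_um = c(12, 12)),
    n_particles = 4000, dt_s = dt, image_shape = c(256, 256), seed = 8
  )
  pfr <- piv_displacement(spr$frame_a, spr$frame_b, piv_cascade,
                          pixel_size_um = 0.0938, dt_s = dt)
  fsr <- cortical_flow_speed(list(pfr), ct, band_width_um = band)
  expect_lt(abs(fsr$tangential_um_per_min),
            0.1 * abs(fsr$normal_um_per_min))
  expect_lt(fsr$normal_um_per_min, 0)   # contraction: inward
  # band narrower than the grid spacing is rejected with guidance
  expect_error(cortical_flow_speed(list(pf), ct, band_width_um = 0.5),
               "grid spacing")
})
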