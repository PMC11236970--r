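test_that("contour extraction recovers rendered geometry to sub-pixel", {
  # plain circle, R = 20 um
  ct <- circle_contour(R = 20, center = c(28, 28))
  fr <- render_two_channel_frame(ct, noise = TRUE, seed = 1)
  ce <- extract_contour(fr$membrane, 0.0938)
  expect_lt(abs(radial_decomposition(ce)$R_mean_um - 20), 0.1)
  # two-mode ellipse-like shape: vertexwise error below one pixel
  ct2 <- mode_contour(R = 18, eps = 0.04, m = 2, center = c(26, 26))
  fr2 <- render_two_channel_frame(ct2, noise = TRUE, seed = 2)
  ce2 <- extract_contour(fr2$membrane, 0.0938)
  rd_t <- radial_decomposition(ct2); rd_e <- radial_decomposition(ce2)
  expect_lt(max(abs(rd_t$R_um - rd_e$R_um)), 0.0938)
})

test_that("blank or broken membrane images are rejected", {
  expect_error(extract_contour(matrix(0.1, 128, 128), 0.0938), "no membrane")
  # ring with a 60-degree gap
  ct <- circle_contour(R = 8, center = c(12, 12))
  fr <- render_two_channel_frame(ct, noise = FALSE)
  img <- fr$membrane
  nr <- nrow(img); nc <- ncol(img)
  X <- matrix(rep(seq_len(nc), each = nr), nr) * 0.0938
  Y <- matrix(rep(seq_len(nr), times = nc), nr) * 0.0938
  ang <- atan2(Y - 12, X - 12)
  img[abs(ang) < pi / 6] <- 0.1
  expect_error(extract_contour(img, 0.0938), "gap")
})

test_that("radial decomposition reproduces imposed modes", {
  th <- theta_grid()
  ct <- mode_contour(R = 20, eps = 0.05, m = 2)
  rd <- radial_decomposition(ct)
  expect_lt(max(abs(rd$u_um - 20 * 0.05 * cos(2 * rd$theta))), 1e-6)
  expect_equal(mean(rd$u_um), 0, tolerance = 1e-12)
  circ <- circle_contour()
  expect_lt(max(abs(radial_decomposition(circ)$u_um)), 1e-9)
  # non-star-shaped (notched) contour is refused
  notch <- membrane_contour(c(0, 10, 10, 6, 6, 4, 4, 0),
                            c(0, 0, 10, 10, 3, 3, 10, 10))
  expect_error(radial_decomposition(notch), "star-shaped")
})

test_that("shape metrics match closed forms", {
  m <- shape_metrics(circle_contour())
  expect_equal(m$circularity, 1, tolerance = 1e-4)
  expect_lt(m$eps_memb, 1e-4)
  sq <- membrane_contour(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(4 * pi * sq$area_um2 / sq$perimeter_um^2, pi / 4,
               tolerance = 1e-12)
  expect_equal(1 - 4 * pi * sq$area_um2 / sq$perimeter_um^2, 1 - pi / 4,
               tolerance = 1e-12)
  # ellipse a/b = 2 against the dense-quadrature perimeter oracle
  th <- theta_grid(2000)
  a <- 20; b <- 10
  el <- membrane_contour(a * cos(th), b * sin(th))
  C_poly <- 4 * pi * el$area_um2 / el$perimeter_um^2
  C_oracle <- 4 * pi * (pi * a * b) / ellipse_perimeter_oracle(a, b)^2
  expect_equal(C_poly, C_oracle, tolerance = 1e-4)
})

test_that("isoperimetric inequality holds over generated ensembles", {
  for (i in 1:20) {
    ser <- sample_contour_series(15, kappa = 1, gamma = 1, n_modes = 16,
                                 u_rms_um = 0.6, n_frames = 1, seed = i)
    m <- shape_metrics(ser$contours[[1]])
    expect_lte(m$circularity, 1)
  }
})

test_that("polarity is invariant under rigid motions and eps under scaling", {
  th <- theta_grid()
  I <- 1 + 0.5 * cos(th - 0.7)
  ct <- circle_contour(R = 15, center = c(20, 20))
  p0 <- polarity_from_intensity(ct, I)
  # translation
  ct_t <- membrane_contour(ct$x + 7.3, ct$y - 2.1)
  expect_equal(polarity_from_intensity(ct_t, I), p0, tolerance = 1e-12)
  # rotation of the whole scene (vertices and intensity pattern together)
  ang <- 1.1
  xr <- cos(ang) * (ct$x - 20) - sin(ang) * (ct$y - 20) + 20
  yr <- sin(ang) * (ct$x - 20) + cos(ang) * (ct$y - 20) + 20
  expect_equal(polarity_from_intensity(membrane_contour(xr, yr), I), p0,
               tolerance = 1e-12)
  # eps_memb invariant under uniform scaling, exactly
  ct2 <- mode_contour(R = 10, eps = 0.06, m = 3)
  ct2s <- membrane_contour(ct2$x * 3.7, ct2$y * 3.7)
  expect_equal(shape_metrics(ct2s)$eps_memb, shape_metrics(ct2)$eps_memb,
               tolerance = 1e-12)
})

test_that("band-sampled actin polarity matches the painted pattern", {
  ct <- circle_contour(R = 18, center = c(26, 26))
  for (tgt in c(0, 0.15, 0.30)) {
    pol <- make_polarized_cortex(ct, tgt, profile = "cosine")
    fr <- render_two_channel_frame(
      ct, cortex_weights = pol$intensity,
      intensities = list(I_S = 7.7, I_V = 1, I_out = 0.1, I_memb = 4),
      noise = TRUE, seed = round(100 * tgt) + 1
    )
    ce <- extract_contour(fr$membrane, 0.0938)
    expect_lt(abs(actin_polarity(ce, fr$actin, 0.0938) - tgt), 0.02)
  }
  expect_error(actin_polarity(ct, matrix(0, 600, 600), 0.0938), "all-zero")
})

test_that("timeseries maxima and baseline behave as specified", {
  # monotone deformation ramp: maximum at the final frame
  ramp <- seq(0.2, 1, length.out = 5)
  ser <- sample_contour_series(20, kappa = 1, gamma = 0, n_frames = 5,
                               u_rms_um = 1.2, amplitude_scale = ramp,
                               fixed_shape = TRUE, seed = 3)
  ts <- metric_timeseries(ser$contours, frame_interval_s = 6)
  expect_equal(which.max(ts$eps_memb), 5)
  expect_equal(attr(ts, "eps_memb_max"), max(ts$eps_memb))
  # static scene: maximum equals the first-frame value
  ct <- circle_contour()
  ts0 <- metric_timeseries(list(ct, ct, ct))
  expect_equal(attr(ts0, "eps_memb_max"), ts0$eps_memb[1])
  # baseline subtraction zeroes the reference frame
  tsb <- metric_timeseries(ser$contours, baseline_frame = 1)
  expect_equal(tsb$eps_memb[1], 0)
})
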