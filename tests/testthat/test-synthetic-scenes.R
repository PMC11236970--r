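test_that("contour sampling follows the Helfrich spectrum law", {
  # kappa-dominated ensemble: per-mode power proportional to q^-4
  ser <- sample_contour_series(20, kappa = 1, gamma = 0, n_modes = 12,
                               n_frames = 500, seed = 11)
  u <- do.call(rbind, lapply(ser$contours, function(ct) {
    radial_decomposition(ct)$u_um
  }))
  sp <- deformation_power_spectrum(u)
  expected <- 360 * ser$sigma_q^2 / 2
  rel <- sp$power[2:12] / expected
  expect_lt(max(abs(rel - 1)), 0.10)
  expect_equal(fit_scaling_exponent(sp, q_range = c(2, 12)), 4,
               tolerance = 0.1)

  serg <- sample_contour_series(20, kappa = 0, gamma = 1, n_modes = 12,
                                n_frames = 500, seed = 12)
  ug <- do.call(rbind, lapply(serg$contours, function(ct) {
    radial_decomposition(ct)$u_um
  }))
  expect_equal(fit_scaling_exponent(deformation_power_spectrum(ug),
                                    q_range = c(2, 12)), 2, tolerance = 0.1)
})

test_that("zero-amplitude contours are circles and low modes are excluded", {
  ser <- sample_contour_series(15, kappa = 1, gamma = 0, n_frames = 1,
                               u_rms_um = 0, seed = 1)
  m <- shape_metrics(ser$contours[[1]])
  expect_equal(m$circularity, 1, tolerance = 1e-4)
  expect_equal(m$R_mean_um, 15, tolerance = 1e-9)
  q <- as.integer(names(ser$truth$mode_amplitudes))
  expect_true(all(q >= 2))
  expect_error(scene_truth(10, mode_amplitudes = stats::setNames(complex(1), "1")),
               "translation")
  # oversize amplitudes exhaust the resampling budget
  expect_error(
    sample_contour_series(10, kappa = 1, gamma = 0, u_rms_um = 30,
                          seed = 2, max_attempts = 5),
    "attempts"
  )
})

test_that("renderer enforces intensity ordering and records geometry", {
  ct <- circle_contour(R = 10, center = c(14, 14))
  expect_error(
    render_two_channel_frame(ct, intensities = list(I_S = 1, I_V = 1,
                                                    I_out = 2, I_memb = 1)),
    "brightest"
  )
  expect_warning(
    render_two_channel_frame(ct, cortex_thickness_um = 0.05, noise = FALSE),
    "sub-resolution"
  )
  expect_error(
    render_two_channel_frame(ct, image_shape = c(50, 50)),
    "too small"
  )
})

test_that("equal interior and exterior intensities give zero peak shift", {
  # I_V = I_out: the blurred cortex peak sits exactly at -h/2, so the
  # two-peak distance is h/2 and the solved shift delta is zero
  ct <- circle_contour(R = 10, center = c(14, 14))
  fr <- render_two_channel_frame(
    ct, cortex_thickness_um = 0.4, psf_sigma_um = 0.119,
    intensities = list(I_S = 4, I_V = 0.5, I_out = 0.5, I_memb = 4),
    noise = FALSE
  )
  est <- estimate_cortex_thickness(ct, fr$membrane, fr$actin, 0.0938,
                                   sigma_um = 0.119)
  expect_equal(est$log_ratio, 0, tolerance = 1e-6)
  expect_equal(est$delta_shift_um, 0, tolerance = 0.02)
  expect_equal(est$h_um, 2 * est$delta_um, tolerance = 1e-9)
})

test_that("speckle pairs carry machine-exact analytic truth", {
  sp <- make_speckle_pair(list(type = "radial_contraction", k_per_s = 0.002,
                               center_um = c(12, 12)),
                          dt_s = 6, seed = 3)
  expect_equal(sp$divergence_per_s, -0.004)
  expect_equal(sp$truth$u_um, -0.002 * (sp$truth$x_um - 12) * 6,
               tolerance = 1e-12)
  sw <- make_speckle_pair(list(type = "swirl", omega_per_s = 0.01,
                               center_um = c(12, 12)), dt_s = 6, seed = 3)
  expect_equal(sw$divergence_per_s, 0)
  expect_error(
    make_speckle_pair(list(type = "translation", v_um_s = c(10, 0)),
                      dt_s = 6, search_window_px = 64, seed = 1),
    "search window"
  )
  expect_error(
    make_speckle_pair(list(type = "vortex_sheet"), seed = 1),
    "unknown flow"
  )
})

test_that("filament textures realize the requested nematic order", {
  tx1 <- make_filament_texture(1, n_filaments = 50, seed = 5)
  expect_equal(tx1$order_realized, 1)
  tx0 <- make_filament_texture(0, n_filaments = 900, seed = 5)
  expect_lt(abs(tx0$order_realized), 3 / sqrt(900))
  expect_error(make_filament_texture(0.5, n_filaments = 0), "filament")
})

test_that("polarized cortex profiles hit the target polarity exactly", {
  ct <- circle_contour()
  expect_equal(polarity_from_intensity(ct, rep(1, 360)), 0, tolerance = 1e-12)
  expect_equal(polarity_from_intensity(ct, c(1, rep(0, 359))), 1,
               tolerance = 1e-9)
  # half circle lit: arc-centroid integral gives 2/pi; the polygon sum at
  # 1 degree resolution matches it to discretization accuracy
  th <- theta_grid()
  I_half <- as.numeric(abs(th) <= pi / 2)
  ct0 <- membrane_contour(20 * cos(th) + 28, 20 * sin(th) + 28)
  expect_equal(polarity_from_intensity(ct0, I_half), 2 / pi,
               tolerance = 6e-3)
  for (tgt in c(0.05, 0.2, 0.45)) {
    pol <- make_polarized_cortex(ct, tgt, profile = "cosine")
    expect_equal(pol$polarity_realized, tgt, tolerance = 1e-6)
  }
  pol_step <- make_polarized_cortex(ct, 0.6, profile = "step")
  expect_equal(pol_step$polarity_realized, 0.6, tolerance = 1e-6)
  expect_error(make_polarized_cortex(ct, 0.9, profile = "cosine"),
               "max attainable")
})

test_that("bead images respect the separation precondition", {
  bd <- make_bead_image(8, seed = 2)
  D <- as.matrix(stats::dist(bd$centers_um))
  diag(D) <- Inf
  expect_gte(min(D), 6 * 0.119)
  expect_equal(bd$sigma_true_um, 0.119)
  expect_error(
    make_bead_image(500, image_shape = c(64, 64), seed = 1),
    "separation"
  )
})

test_that("scenes round-trip through TIFF + JSON sidecar", {
  dir <- withr::local_tempdir()
  ser <- sample_contour_series(12, kappa = 1, gamma = 0, n_frames = 2,
                               seed = 9)
  fr <- lapply(ser$contours, function(ct) {
    render_two_channel_frame(ct, pixel_size_um = 0.2, noise = FALSE)
  })
  scene <- list(
    membrane = lapply(fr, `[[`, "membrane"),
    actin = lapply(fr, `[[`, "actin"),
    truth = ser$truth, pixel_size_um = 0.2, frame_interval_s = 6
  )
  write_scene(scene, dir)
  back <- read_scene(dir)
  expect_equal(length(back$membrane), 2)
  expect_equal(back$pixel_size_um, 0.2)
  expect_equal(back$truth$radius_um, 12)
  expect_equal(back$truth$mode_amplitudes, ser$truth$mode_amplitudes,
               tolerance = 1e-9)
  # 16-bit quantisation: intensities preserved to ~2e-5 of full scale
  expect_equal(back$membrane[[1]], scene$membrane[[1]],
               tolerance = 1e-3)
})

test_that("render + extract round-trip stays within a pixel of truth", {
  ser <- sample_contour_series(16, kappa = 1, gamma = 0, n_frames = 1,
                               u_rms_um = 0.4, seed = 21)
  ct <- ser$contours[[1]]
  fr <- render_two_channel_frame(ct, noise = TRUE, seed = 4)
  ce <- extract_contour(fr$membrane, 0.0938)
  rd_t <- radial_decomposition(ct)
  rd_e <- radial_decomposition(ce)
  # radial Hausdorff distance below one pixel
  expect_lt(max(abs(rd_t$R_um - rd_e$R_um)), 0.0938)
})
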