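#' Ground-truth record for a synthetic liposome scene
#'
#' Collects everything the generator knows exactly about a scene so analysis
#' results can be scored against truth: radius, complex angular mode
#' amplitudes (µm), cortex thickness, PSF width, polarity, nematic order,
#' prescribed flow divergence, and the seed.
#'
#' @param radius_um liposome radius (µm), > 0.
#' @param mode_amplitudes named complex vector, names are integer angular
#'   mode numbers q >= 2 (q = 0 area and q = 1 translation modes are
#'   excluded from deformation by construction).
#' @param cortex_thickness_um cortex thickness h (µm), >= 0.
#' @param psf_sigma_um PSF standard deviation (µm), >= 0.
#' @param polarity_true actin polarity in \[0, 1\].
#' @param order_param_true nematic order parameter in \[-1, 1\].
#' @param flow_divergence_per_s prescribed flow divergence (1/s).
#' @param seed integer seed the scene was drawn with.
#' @return object of class `scene_truth`.
#' @export
scene_truth <- function(radius_um, mode_amplitudes = complex(0),
                        cortex_thickness_um = 0, psf_sigma_um = 0,
                        polarity_true = NA_real_, order_param_true = NA_real_,
                        flow_divergence_per_s = NA_real_, seed = NA_integer_) {
  stopifnot(radius_um > 0, cortex_thickness_um >= 0, psf_sigma_um >= 0)
  if (!is.na(order_param_true)) stopifnot(abs(order_param_true) <= 1)
  q <- as.integer(names(mode_amplitudes))
  if (length(q) && any(q < 2)) {
    stop("mode q = 0 (area) and q = 1 (translation) are excluded from deformation")
  }
  structure(
    list(
      radius_um = radius_um, mode_amplitudes = mode_amplitudes,
      cortex_thickness_um = cortex_thickness_um, psf_sigma_um = psf_sigma_um,
      polarity_true = polarity_true, order_param_true = order_param_true,
      flow_divergence_per_s = flow_divergence_per_s, seed = seed
    ),
    class = "scene_truth"
  )
}

# evaluate r(theta) = R + sum_q Re[a_q e^{i q theta}] for a named complex
# amplitude vector
.modes_to_radius <- function(radius_um, amps, theta) {
  r <- rep(radius_um, length(theta))
  q <- as.integer(names(amps))
  for (k in seq_along(q)) {
    r <- r + Re(amps[k] * exp(1i * q[k] * theta))
  }
  r
}

#' Sample a series of fluctuating liposome contours
#'
#' Draws closed contours \eqn{r(\theta) = R + \sum_q Re[a_q e^{iq\theta}]}
#' with independent complex mode amplitudes whose variance follows the
#' Helfrich-form spectrum \eqn{\langle|a_q|^2\rangle \propto
#' (\kappa q^4 + \gamma q^2)^{-1}}.  `kappa`-dominated ensembles produce a
#' \eqn{q^{-4}} power spectrum (elasticity/bending regime),
#' `gamma`-dominated ensembles \eqn{q^{-2}} (tension regime).  Modes q = 0
#' and q = 1 are excluded (area and centroid-translation modes; the analysis
#' measures shape, not size or position).
#'
#' @param radius_um mean radius R (µm).
#' @param kappa,gamma non-negative spectrum coefficients (relative units;
#'   only their ratio and the overall amplitude matter); not both zero.
#' @param n_modes highest mode q included (modes 2..n_modes are drawn).
#' @param n_frames number of independent frames.
#' @param u_rms_um target root-mean-square deformation amplitude per frame
#'   (sets the overall spectrum scale).  Default 2% of the radius, the scale
#'   of cortex-driven deformations on ~20 µm liposomes.
#' @param n_theta vertices per contour.
#' @param amplitude_scale optional vector of per-frame multipliers applied
#'   to the drawn amplitudes (e.g. a contraction ramp); length `n_frames`.
#' @param fixed_shape if `TRUE` one mode set is drawn and reused for every
#'   frame (deformation growing smoothly under `amplitude_scale`); if
#'   `FALSE` (default) frames are independent draws.
#' @param seed integer seed.
#' @param max_attempts resampling budget for rejecting self-intersecting
#'   contours.
#' @return list with `contours` (list of [membrane_contour]), `truth` (a
#'   [scene_truth]; `mode_amplitudes` holds the first frame's draw),
#'   `amplitudes` (list of per-frame complex amplitude vectors) and
#'   `sigma_q` (the per-mode sampling standard deviations, µm).
#' @export
sample_contour_series <- function(radius_um, kappa = 1, gamma = 0,
                                  n_modes = 24L, n_frames = 1L,
                                  u_rms_um = 0.02 * radius_um,
                                  n_theta = 360L, amplitude_scale = NULL,
                                  fixed_shape = FALSE, seed = 1L,
                                  max_attempts = 50L) {
  stopifnot(kappa >= 0, gamma >= 0, kappa + gamma > 0,
            n_modes >= 2, n_frames >= 1)
  q <- 2:n_modes
  shape <- 1 / (kappa * q^4 + gamma * q^2)
  # E Var_theta(u) = sum_q E|a_q|^2 / 2; scale so rms(u) = u_rms_um
  sigma_q <- sqrt(shape / sum(shape) * 2 * u_rms_um^2)
  names(sigma_q) <- q
  if (is.null(amplitude_scale)) amplitude_scale <- rep(1, n_frames)
  stopifnot(length(amplitude_scale) == n_frames)
  theta <- seq(-pi, pi, length.out = n_theta + 1L)[-1L]

  draw <- function() {
    a <- complex(
      real = stats::rnorm(length(q), sd = sigma_q / sqrt(2)),
      imaginary = stats::rnorm(length(q), sd = sigma_q / sqrt(2))
    )
    names(a) <- q
    a
  }
  with_seed(seed, {
    amplitudes <- vector("list", n_frames)
    contours <- vector("list", n_frames)
    base <- if (fixed_shape) draw() else NULL
    for (f in seq_len(n_frames)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        a <- (if (fixed_shape) base else draw()) * amplitude_scale[f]
        r <- .modes_to_radius(radius_um, a, theta)
        if (min(r) <= 0.2 * radius_um) next
        cont <- membrane_contour(r * cos(theta) + radius_um * 1.4,
                                 r * sin(theta) + radius_um * 1.4,
                                 frame = f, check_simple = FALSE)
        # star-shaped curves with r > 0 are simple by construction
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(
          "could not draw a simple contour in %d attempts (amplitudes too large)",
          max_attempts
        ))
      }
      amplitudes[[f]] <- a
      contours[[f]] <- cont
    }
    list(
      contours = contours,
      truth = scene_truth(radius_um, mode_amplitudes = amplitudes[[1]],
                          seed = seed),
      amplitudes = amplitudes,
      sigma_q = sigma_q
    )
  })
}

# Analytic blurred radial actin profile: step model (exterior I_out for
# s > 0, cortex plateau I_S on (-h, 0], interior I_V below) convolved with a
# Gaussian PSF of width sigma along the normal.  s is the signed distance
# outward from the membrane position.
cortex_profile_model <- function(s, h, sigma, I_S, I_V, I_out) {
  if (sigma <= 0) {
    out <- ifelse(s > 0, I_out, ifelse(s > -h, I_S, I_V))
    return(out)
  }
  I_V * stats::pnorm((-h - s) / sigma) +
    I_S * (stats::pnorm(-s / sigma) - stats::pnorm((-h - s) / sigma)) +
    I_out * (1 - stats::pnorm(-s / sigma))
}

# Poisson shot noise (scaled by a camera gain) plus Gaussian read noise.
add_poisson_gaussian_noise <- function(img, gain = 0.01, read_noise_sd = 0.02) {
  counts <- pmax(img, 0) / gain
  img_noisy <- stats::rpois(length(counts), counts) * gain
  img_noisy <- img_noisy + stats::rnorm(length(counts), sd = read_noise_sd)
  matrix(img_noisy, nrow(img), ncol(img))
}

#' Render a two-channel (membrane, actin) liposome frame
#'
#' The membrane channel is a thin fluorescent shell on the contour blurred
#' by the Gaussian PSF; the actin channel is a cortex shell of thickness `h`
#' immediately inside the membrane over a uniform interior (volume)
#' intensity `I_V` and exterior `I_out`, blurred by the PSF, with optional
#' Poisson-Gaussian camera noise.  The blur is applied analytically along
#' the radial direction (exact for a straight edge; curvature corrections
#' are of order sigma/R and negligible here).
#'
#' @param contour a [membrane_contour] (µm coordinates).
#' @param cortex_thickness_um cortex thickness h (µm).  Sub-pixel values are
#'   valid and intended (a warning notes the sub-resolution regime).
#' @param psf_sigma_um PSF standard deviation (µm).
#' @param intensities named list/vector with `I_S` (cortex plateau), `I_V`
#'   (interior volume), `I_out` (exterior), `I_memb` (membrane peak).
#'   Defaults use a surface-to-volume ratio I_S/I_V = 4, mid-range of the
#'   ratios seen in well-formed cortices (~1.8-7.7).
#' @param cortex_weights optional per-vertex multiplicative modulation of
#'   the cortex (shell) intensity, e.g. from [make_polarized_cortex]; length
#'   must match the contour.
#' @param noise logical; apply Poisson-Gaussian noise (default TRUE; the
#'   default gain gives SNR ~ 20 at the cortex peak, typical of
#'   spinning-disk confocal data).
#' @param gain,read_noise_sd noise-model parameters.
#' @param pixel_size_um pixel size (default 0.0938 µm/px).
#' @param image_shape `c(rows, cols)`; default fits the contour plus a 3
#'   sigma + 2 µm margin.
#' @param seed seed for the noise draw.
#' @return list with `membrane`, `actin` (matrices) and `offset_um`
#'   (the physical coordinate of the image origin, always c(0, 0) here).
#' @export
render_two_channel_frame <- function(contour,
                                     cortex_thickness_um = 0.29,
                                     psf_sigma_um = 0.119,
                                     intensities = list(I_S = 4, I_V = 1,
                                                        I_out = 0.1,
                                                        I_memb = 4),
                                     cortex_weights = NULL,
                                     noise = TRUE, gain = 0.01,
                                     read_noise_sd = 0.02,
                                     pixel_size_um = 0.0938,
                                     image_shape = NULL, seed = 1L) {
  stopifnot(pixel_size_um > 0, cortex_thickness_um >= 0, psf_sigma_um >= 0)
  I_S <- intensities$I_S; I_V <- intensities$I_V
  I_out <- intensities$I_out; I_memb <- intensities$I_memb
  if (I_out >= I_S) {
    stop("I_out >= I_S: the cortex must be the brightest radial feature")
  }
  if (cortex_thickness_um > 0 && cortex_thickness_um < pixel_size_um) {
    warning("cortex thickness below one pixel: sub-resolution regime")
  }
  margin <- 3 * psf_sigma_um + 2
  if (is.null(image_shape)) {
    image_shape <- c(
      ceiling((max(contour$y) + margin) / pixel_size_um),
      ceiling((max(contour$x) + margin) / pixel_size_um)
    )
  } else {
    if (max(contour$x) + margin > image_shape[2] * pixel_size_um ||
        max(contour$y) + margin > image_shape[1] * pixel_size_um ||
        min(contour$x) < margin || min(contour$y) < margin) {
      stop("image too small to contain the contour plus a 3 sigma margin")
    }
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  cx <- unname(contour$center["x"]); cy <- unname(contour$center["y"])
  x <- (seq_len(nc) - 0.5) * pixel_size_um
  y <- (seq_len(nr) - 0.5) * pixel_size_um
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  th <- atan2(Y - cy, X - cx)
  rr <- sqrt((X - cx)^2 + (Y - cy)^2)
  # contour radius at each pixel angle (star-shaped contour)
  th_v <- atan2(contour$y - cy, contour$x - cx)
  r_v <- sqrt((contour$x - cx)^2 + (contour$y - cy)^2)
  Rth <- matrix(periodic_interp(th_v, r_v, as.vector(th)), nr, nc)
  s <- rr - Rth                                 # signed distance, + outside
  sig <- max(psf_sigma_um, 1e-6)

  # evaluate the radial profiles through a fine 1D lookup (ds = sigma/50)
  s_max <- cortex_thickness_um + 6 * sig + 2 * pixel_size_um
  sg <- seq(-s_max, s_max, by = sig / 50)
  s_cl <- pmin(pmax(s, -s_max), s_max)
  lut <- function(vals) {
    matrix(stats::approx(sg, vals, xout = as.vector(s_cl), rule = 2)$y,
           nr, nc)
  }
  membrane <- lut(I_memb * exp(-sg^2 / (2 * sig^2)) + I_out)
  if (is.null(cortex_weights)) {
    actin <- lut(cortex_profile_model(sg, cortex_thickness_um, psf_sigma_um,
                                      I_S, I_V, I_out))
  } else {
    stopifnot(length(cortex_weights) == length(contour$x))
    w <- matrix(periodic_interp(th_v, cortex_weights, as.vector(th)), nr, nc)
    # modulate only the shell's contrast above the interior level
    base <- lut(cortex_profile_model(sg, cortex_thickness_um, psf_sigma_um,
                                     I_V, I_V, I_out))
    shell <- lut(cortex_profile_model(sg, cortex_thickness_um, psf_sigma_um,
                                      I_S, I_V, I_out)) - base
    actin <- base + w * shell
  }
  if (noise) {
    with_seed(seed, {
      membrane <- add_poisson_gaussian_noise(membrane, gain, read_noise_sd)
      actin <- add_poisson_gaussian_noise(actin, gain, read_noise_sd)
    })
  }
  list(membrane = membrane, actin = actin, offset_um = c(0, 0))
}

# analytic flow displacement over dt (u in um): flow specs for speckle pairs
flow_displacement <- function(flow, x_um, y_um, dt_s) {
  switch(flow$type,
    translation = {
      list(u = rep(flow$v_um_s[1] * dt_s, length(x_um)),
           v = rep(flow$v_um_s[2] * dt_s, length(x_um)),
           div_per_s = 0)
    },
    radial_contraction = {
      cx <- flow$center_um[1]; cy <- flow$center_um[2]
      list(u = -flow$k_per_s * (x_um - cx) * dt_s,
           v = -flow$k_per_s * (y_um - cy) * dt_s,
           div_per_s = -2 * flow$k_per_s)
    },
    swirl = {
      cx <- flow$center_um[1]; cy <- flow$center_um[2]
      a <- flow$omega_per_s * dt_s
      dx <- x_um - cx; dy <- y_um - cy
      list(u = dx * cos(a) - dy * sin(a) - dx,
           v = dx * sin(a) + dy * cos(a) - dy,
           div_per_s = 0)
    },
    stop(sprintf("unknown flow type '%s' (use translation, radial_contraction or swirl)",
                 flow$type))
  )
}

#' Generate a speckle image pair advected by a known flow
#'
#' Renders Gaussian speckle particles, advects them exactly by a prescribed
#' flow over one frame interval, and returns the analytically known
#' displacement field sampled on a PIV-style grid, giving PIV analysis a
#' fixture with machine-exact truth.
#'
#' @param flow list describing the flow: `list(type = "translation",
#'   v_um_s = c(vx, vy))`, `list(type = "radial_contraction", k_per_s,
#'   center_um = c(x, y))`, or `list(type = "swirl", omega_per_s,
#'   center_um)`.
#' @param n_particles number of speckles (>= 100).
#' @param dt_s frame interval (s).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um pixel size.
#' @param grid_spacing_px spacing of the truth grid.
#' @param particle_sigma_px Gaussian speckle width.
#' @param search_window_px if given, error when the true displacement
#'   exceeds half this window anywhere.
#' @param noise,gain,read_noise_sd camera noise model (see
#'   [render_two_channel_frame]).
#' @param seed integer seed.
#' @return list with `frame_a`, `frame_b`, `truth` (data.frame `x_um`,
#'   `y_um`, `u_um`, `v_um`) and `divergence_per_s` (spatially uniform for
#'   the supported flows).
#' @export
make_speckle_pair <- function(flow, n_particles = 3000L, dt_s = 6,
                              image_shape = c(256L, 256L),
                              pixel_size_um = 0.0938,
                              grid_spacing_px = 16L,
                              particle_sigma_px = 1.2,
                              search_window_px = NULL,
                              noise = FALSE, gain = 0.01,
                              read_noise_sd = 0.02, seed = 1L) {
  stopifnot(n_particles >= 100)
  nr <- image_shape[1]; nc <- image_shape[2]
  w_um <- nc * pixel_size_um; h_um <- nr * pixel_size_um
  with_seed(seed, {
    px <- stats::runif(n_particles, 0, w_um)
    py <- stats::runif(n_particles, 0, h_um)
    amp <- stats::runif(n_particles, 0.5, 1)
    disp <- flow_displacement(flow, px, py, dt_s)
    if (!is.null(search_window_px)) {
      max_px <- max(abs(c(disp$u, disp$v))) / pixel_size_um
      if (max_px > search_window_px / 2) {
        stop(sprintf(
          "flow displacement %.1f px exceeds half the %d px search window",
          max_px, search_window_px
        ))
      }
    }
    frame_a <- render_speckles(px, py, amp, image_shape, pixel_size_um,
                               particle_sigma_px)
    frame_b <- render_speckles(px + disp$u, py + disp$v, amp, image_shape,
                               pixel_size_um, particle_sigma_px)
    if (noise) {
      frame_a <- add_poisson_gaussian_noise(frame_a, gain, read_noise_sd)
      frame_b <- add_poisson_gaussian_noise(frame_b, gain, read_noise_sd)
    }
    gx <- seq(grid_spacing_px / 2, nc - grid_spacing_px / 2,
              by = grid_spacing_px) * pixel_size_um
    gy <- seq(grid_spacing_px / 2, nr - grid_spacing_px / 2,
              by = grid_spacing_px) * pixel_size_um
    G <- expand.grid(x_um = gx, y_um = gy)
    gd <- flow_displacement(flow, G$x_um, G$y_um, dt_s)
    truth <- data.frame(x_um = G$x_um, y_um = G$y_um,
                        u_um = gd$u, v_um = gd$v)
    list(frame_a = frame_a, frame_b = frame_b, truth = truth,
         divergence_per_s = gd$div_per_s)
  })
}

# Gaussian splat rendering of point particles (sub-pixel positions).
render_speckles <- function(x_um, y_um, amp, image_shape, pixel_size_um,
                            sigma_px) {
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(0, nr, nc)
  half <- ceiling(3 * sigma_px)
  rows <- y_um / pixel_size_um + 0.5
  cols <- x_um / pixel_size_um + 0.5
  for (k in seq_along(x_um)) {
    r0 <- round(rows[k]); c0 <- round(cols[k])
    if (r0 + half < 1 || r0 - half > nr || c0 + half < 1 || c0 - half > nc) next
    ri <- max(1, r0 - half):min(nr, r0 + half)
    ci <- max(1, c0 - half):min(nc, c0 + half)
    gr <- exp(-(ri - rows[k])^2 / (2 * sigma_px^2))
    gc <- exp(-(ci - cols[k])^2 / (2 * sigma_px^2))
    img[ri, ci] <- img[ri, ci] + amp[k] * outer(gr, gc)
  }
  img
}

#' Generate a filament texture with a controlled nematic order parameter
#'
#' Draws straight filaments whose orientations follow a wrapped-normal
#' distribution on the doubled angle chosen so that the expected order
#' parameter \eqn{\langle\cos 2\theta\rangle} equals the target; the
#' realised per-draw value is recorded as truth.
#'
#' @param order_param_target target order in \[0, 1\] (1 = all aligned).
#' @param n_filaments number of filaments (> 0).
#' @param length_px filament length in pixels.
#' @param image_shape `c(rows, cols)`.
#' @param width_px Gaussian width of the rendered filaments.
#' @param mean_angle mean filament direction (radians).
#' @param seed integer seed.
#' @return list with `image`, `angles` (per-filament orientations, radians),
#'   `order_realized` (mean of cos 2 theta over the drawn filaments,
#'   relative to the mean angle).
#' @export
make_filament_texture <- function(order_param_target, n_filaments = 400L,
                                  length_px = 30, image_shape = c(256L, 256L),
                                  width_px = 1.2, mean_angle = 0, seed = 1L) {
  stopifnot(order_param_target >= 0, order_param_target <= 1)
  if (n_filaments < 1) stop("degenerate texture: no filaments")
  nr <- image_shape[1]; nc <- image_shape[2]
  with_seed(seed, {
    if (order_param_target >= 1) {
      th <- rep(mean_angle, n_filaments)
    } else if (order_param_target <= 0) {
      th <- stats::runif(n_filaments, -pi / 2, pi / 2)
    } else {
      # E cos(phi) = exp(-s^2/2) for wrapped-normal phi = 2 theta
      s <- sqrt(-2 * log(order_param_target))
      th <- mean_angle + stats::rnorm(n_filaments, sd = s / 2)
    }
    cx <- stats::runif(n_filaments, 1, nc)
    cy <- stats::runif(n_filaments, 1, nr)
    img <- matrix(0, nr, nc)
    step <- 0.5
    ns <- max(2L, ceiling(length_px / step))
    ts <- seq(-length_px / 2, length_px / 2, length.out = ns)
    half <- ceiling(3 * width_px)
    for (k in seq_len(n_filaments)) {
      # filament direction in image coordinates (y down, angle CCW from +x)
      xs <- cx[k] + ts * cos(th[k])
      ys <- cy[k] + ts * sin(th[k])
      keep <- xs > -half & xs < nc + half & ys > -half & ys < nr + half
      xs <- xs[keep]; ys <- ys[keep]
      for (j in seq_along(xs)) {
        r0 <- round(ys[j]); c0 <- round(xs[j])
        if (r0 + half < 1 || r0 - half > nr ||
            c0 + half < 1 || c0 - half > nc) next
        ri <- max(1, r0 - half):min(nr, r0 + half)
        ci <- max(1, c0 - half):min(nc, c0 + half)
        gr <- exp(-(ri - ys[j])^2 / (2 * width_px^2))
        gc <- exp(-(ci - xs[j])^2 / (2 * width_px^2))
        img[ri, ci] <- img[ri, ci] + outer(gr, gc)
      }
    }
    order_realized <- mean(cos(2 * (th - mean_angle)))
    list(image = img, angles = th, order_realized = order_realized)
  })
}

#' Construct a polarized cortical intensity pattern on a contour
#'
#' Builds per-vertex actin intensities whose intensity-weighted centroid
#' offset, normalised by the mean radius, equals the requested polarity
#' to within 1e-6, by solving for the profile contrast.
#'
#' Two profile families are available: `"cosine"`,
#' \eqn{I(\theta) = 1 + c\cos(\theta - \theta_0)} (maximum attainable
#' polarity 0.5 on a circle), and `"step"`, a lit arc of fractional width
#' `arc_fraction` with dark level `c` solved for (a fully dark complement
#' over a half circle gives polarity \eqn{2/\pi \approx 0.637}; narrower
#' arcs approach 1).
#'
#' @param contour a [membrane_contour].
#' @param polarity_target target polarity in \[0, 1).
#' @param profile `"cosine"` or `"step"`.
#' @param direction_rad direction of the bright pole.
#' @param arc_fraction lit arc fraction for the step profile (default 0.5,
#'   a half circle).
#' @return list with `intensity` (per-vertex), `polarity_realized`,
#'   `contrast` (the solved parameter).
#' @export
make_polarized_cortex <- function(contour, polarity_target,
                                  profile = c("cosine", "step"),
                                  direction_rad = 0, arc_fraction = 0.5) {
  profile <- match.arg(profile)
  stopifnot(polarity_target >= 0, polarity_target < 1)
  th <- atan2(contour$y - contour$center["y"],
              contour$x - contour$center["x"])
  dth <- wrap_angle(th - direction_rad)
  make_I <- switch(profile,
    cosine = function(c) 1 + c * cos(dth),
    step = function(c) ifelse(abs(dth) <= pi * arc_fraction, 1, c)
  )
  pol <- function(c) polarity_from_intensity(contour, make_I(c))
  if (polarity_target == 0) {
    I <- switch(profile, cosine = make_I(0), step = make_I(1))
    return(list(intensity = I, polarity_realized = pol(switch(profile,
      cosine = 0, step = 1)), contrast = switch(profile, cosine = 0, step = 1)))
  }
  # contrast bounds: cosine c in [0,1]; step dark level c in [0,1]
  p_max <- switch(profile, cosine = pol(1), step = pol(0))
  if (polarity_target > p_max + 1e-12) {
    stop(sprintf(
      "polarity %.4f unreachable for %s profile (max attainable %.4f)",
      polarity_target, profile, p_max
    ))
  }
  f <- switch(profile,
    cosine = function(c) pol(c) - polarity_target,
    step = function(c) pol(c) - polarity_target
  )
  interval <- switch(profile, cosine = c(0, 1), step = c(0, 1))
  root <- stats::uniroot(f, interval = interval, tol = 1e-10)$root
  I <- make_I(root)
  list(intensity = I, polarity_realized = pol(root), contrast = root)
}

#' Generate an image of isolated sub-resolution beads
#'
#' Renders well-separated Gaussian spots of known standard deviation for PSF
#' calibration; bead centres are rejection-sampled to a minimum pairwise
#' separation of 6 sigma.
#'
#' @param n_beads number of beads.
#' @param psf_sigma_um true PSF standard deviation (µm).
#' @param pixel_size_um pixel size.
#' @param image_shape `c(rows, cols)`.
#' @param amplitude peak amplitude above background.
#' @param background constant background level.
#' @param noise,gain,read_noise_sd camera noise model.
#' @param seed integer seed.
#' @return list with `image`, `centers_um` (n x 2), `sigma_true_um`.
#' @export
make_bead_image <- function(n_beads = 10L, psf_sigma_um = 0.119,
                            pixel_size_um = 0.0938,
                            image_shape = c(256L, 256L),
                            amplitude = 1, background = 0.05,
                            noise = TRUE, gain = 0.005,
                            read_noise_sd = 0.01, seed = 1L) {
  nr <- image_shape[1]; nc <- image_shape[2]
  sep_um <- 6 * psf_sigma_um
  margin_um <- 5 * psf_sigma_um + 2 * pixel_size_um
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < n_beads) {
      attempts <- attempts + 1L
      if (attempts > 2000L * n_beads) {
        stop("cannot place beads with >= 6 sigma separation in this image")
      }
      x <- stats::runif(1, margin_um, nc * pixel_size_um - margin_um)
      y <- stats::runif(1, margin_um, nr * pixel_size_um - margin_um)
      if (length(xs) == 0 ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= sep_um) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    sig_px <- psf_sigma_um / pixel_size_um
    img <- render_speckles(xs, ys, rep(amplitude, n_beads), image_shape,
                           pixel_size_um, sig_px) + background
    if (noise) img <- add_poisson_gaussian_noise(img, gain, read_noise_sd)
    list(image = img, centers_um = cbind(x = xs, y = ys),
         sigma_true_um = psf_sigma_um)
  })
}
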