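# Shared fixture builders (everything generated in code at test time).

theta_grid <- function(n = 360L) seq(-pi, pi, length.out = n + 1L)[-1L]

circle_contour <- function(R = 20, center = c(28, 28), n = 360L) {
  th <- theta_grid(n)
  membrane_contour(R * cos(th) + center[1], R * sin(th) + center[2])
}

# polar two-mode contour r = R (1 + eps cos(m theta))
mode_contour <- function(R = 20, eps = 0.05, m = 2L, center = c(30, 30),
                         n = 360L) {
  th <- theta_grid(n)
  r <- R * (1 + eps * cos(m * th))
  membrane_contour(r * cos(th) + center[1], r * sin(th) + center[2])
}

# displacement_field built directly from analytic functions on a grid
analytic_field <- function(ufun, vfun, x_um, y_um, dt_s = 1) {
  G <- expand.grid(y = y_um, x = x_um)
  u <- matrix(ufun(G$x, G$y), length(y_um), length(x_um))
  v <- matrix(vfun(G$x, G$y), length(y_um), length(x_um))
  structure(
    list(x_um = x_um, y_um = y_um, u_um = u, v_um = v,
         u_px = u, v_px = v,
         quality = matrix(1, length(y_um), length(x_um)),
         valid = matrix(TRUE, length(y_um), length(x_um)),
         window_cascade = list(), pixel_size_um = 1, dt_s = dt_s),
    class = "displacement_field"
  )
}

# high-accuracy ellipse perimeter by dense numeric quadrature
ellipse_perimeter_oracle <- function(a, b) {
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  stats::integrate(f, 0, 2 * pi, rel.tol = 1e-12)$value
}

# closed-form curvature of the polar curve r(theta)
polar_curvature_oracle <- function(r, rp, rpp) {
  (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
}

# brute-force 1D convolution of the cortex step profile with a Gaussian PSF
# on a fine grid; returns the blurred profile and its peak position
profile_convolution_oracle <- function(h, sigma, I_S, I_V, I_out,
                                       ds = 1e-4, s_max = 3) {
  s <- seq(-s_max, s_max, by = ds)
  f <- ifelse(s > 0, I_out, ifelse(s > -h, I_S, I_V))
  half <- ceiling(5 * sigma / ds)
  k <- stats::dnorm(seq(-half, half) * ds, sd = sigma) * ds
  g <- stats::convolve(f, rev(k), type = "open")
  g <- g[(half + 1):(half + length(s))]
  i0 <- which.max(g)
  ip <- i0 + 0.5 * (g[i0 - 1] - g[i0 + 1]) /
    (g[i0 - 1] - 2 * g[i0] + g[i0 + 1])
  list(s = s, g = g, peak_s = s[1] + (ip - 1) * ds)
}
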