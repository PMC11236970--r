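# Internal geometry / image helpers shared across modules.
#
# Coordinate convention (used everywhere in the package):
#   images are base-R matrices indexed [row, col], origin at the top-left;
#   physical coordinates x = col * pixel_size, y = row * pixel_size with the
#   pixel (r, c) centred at ((c - 0.5) * px, (r - 0.5) * px);
#   angles are measured counter-clockwise from +x in the (x, y) frame.

# convert physical um coordinates to continuous (row, col) pixel-centre units
.um_to_rc <- function(x_um, y_um, pixel_size_um) {
  list(row = y_um / pixel_size_um + 0.5, col = x_um / pixel_size_um + 0.5)
}

# Bilinear interpolation of img at continuous (row, col) positions.
# Positions outside the image clamp to the border.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

# Shoelace signed area; positive = counter-clockwise in the (x, y) frame.
polygon_signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygon_perimeter <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

# Simplicity test for a closed polygon: no two non-adjacent edges intersect.
# O(n^2) vectorised segment-pair test; adequate for contour-sized polygons.
polygon_is_simple <- function(x, y) {
  n <- length(x)
  if (n < 4) return(TRUE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1 & !(i == 1 & j == n)
  }), arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d1 <- cross(x2[i] - x[i], y2[i] - y[i], x[j] - x[i], y[j] - y[i])
  d2 <- cross(x2[i] - x[i], y2[i] - y[i], x2[j] - x[i], y2[j] - y[i])
  d3 <- cross(x2[j] - x[j], y2[j] - y[j], x[i] - x[j], y[i] - y[j])
  d4 <- cross(x2[j] - x[j], y2[j] - y[j], x2[i] - x[j], y2[i] - y[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

# Periodic linear interpolation of values v defined at angles th (radians,
# any order) onto query angles thq.  Used for R(theta) lookups.
periodic_interp <- function(th, v, thq) {
  o <- order(th)
  th <- th[o]; v <- v[o]
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  v_ext <- c(v, v, v)
  stats::approx(th_ext, v_ext, xout = thq, rule = 2)$y
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# Separable Gaussian blur with replicate padding (small sigma, exact kernel).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) {
    rbind(m[rep(1L, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE])
  }
  conv_cols <- function(m) {
    mp <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (s in seq_along(k)) {
      out <- out + k[s] * mp[s:(s + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

# Subpixel 1D peak position by 3-point Gaussian interpolation around index i0
# (log-parabola); falls back to parabolic when log is undefined.
subpixel_peak_1d <- function(v, i0) {
  n <- length(v)
  if (i0 <= 1 || i0 >= n) return(i0)
  a <- v[i0 - 1]; b <- v[i0]; c <- v[i0 + 1]
  if (a > 0 && b > 0 && c > 0 && (b >= a && b >= c)) {
    la <- log(a); lb <- log(b); lc <- log(c)
    den <- la - 2 * lb + lc
    if (den < 0) return(i0 + 0.5 * (la - lc) / den)
  }
  den <- a - 2 * b + c
  if (den == 0) return(i0)
  i0 + 0.5 * (a - c) / den
}

# Draw-with-seed helper: evaluates expr with the given seed, restoring RNG
# state afterwards; NULL seed evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
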