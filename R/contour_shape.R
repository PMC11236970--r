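#' Membrane contour container
#'
#' An ordered, closed, counter-clockwise polygon describing the membrane
#' position in the liposome mid-plane, in physical micrometres.  The
#' constructor computes the centre of mass \eqn{r_c = N^{-1}\sum r_i}, the
#' enclosed area (shoelace formula) and the perimeter, and re-orients the
#' vertex order to counter-clockwise if needed.
#'
#' @param x_um,y_um numeric vectors of vertex coordinates in micrometres.
#'   The polygon is implicitly closed; do not repeat the first vertex.
#' @param frame integer frame index the contour belongs to (optional).
#' @param check_simple logical; verify the polygon does not self-intersect.
#' @return an object of class `membrane_contour` with elements `x`, `y`
#'   (µm), `frame`, `center` (µm), `area_um2`, `perimeter_um`.
#' @export
membrane_contour <- function(x_um, y_um, frame = NA_integer_,
                             check_simple = FALSE) {
  stopifnot(length(x_um) == length(y_um), length(x_um) >= 3)
  if (anyNA(x_um) || anyNA(y_um)) stop("contour vertices contain NA")
  a <- polygon_signed_area(x_um, y_um)
  if (a == 0) stop("degenerate contour: zero enclosed area")
  if (a < 0) {   # re-orient to counter-clockwise
    x_um <- rev(x_um); y_um <- rev(y_um)
    a <- -a
  }
  if (check_simple && !polygon_is_simple(x_um, y_um)) {
    stop("contour is self-intersecting")
  }
  structure(
    list(
      x = x_um, y = y_um, frame = frame,
      center = c(x = mean(x_um), y = mean(y_um)),
      area_um2 = a,
      perimeter_um = polygon_perimeter(x_um, y_um)
    ),
    class = "membrane_contour"
  )
}

#' @export
print.membrane_contour <- function(x, ...) {
  cat(sprintf(
    "<membrane_contour> %d vertices, area %.2f um^2, perimeter %.2f um\n",
    length(x$x), x$area_um2, x$perimeter_um
  ))
  invisible(x)
}

#' Extract the membrane contour from a membrane-channel image
#'
#' Locates the bright membrane ring and traces its intensity ridge: an
#' initial centre/radius estimate (threshold + largest connected component,
#' or a user-supplied circle) seeds radial ray casting; along each of
#' `n_vertices` rays the intensity peak is localised to sub-pixel precision
#' by a three-point Gaussian fit, and the centre is re-estimated and the rays
#' re-cast once so the parameterisation is centred on the contour itself.
#'
#' @param membrane_image numeric matrix, membrane channel.
#' @param pixel_size_um pixel size in µm.
#' @param init optional list with `center_um = c(x, y)` and `radius_um` used
#'   to initialise the search instead of automatic detection.
#' @param n_vertices number of equally spaced angular rays (default 360,
#'   i.e. 1 degree resolution).
#' @param search_fraction rays scan radii in
#'   `[(1 - search_fraction) R0, (1 + search_fraction) R0]`.
#' @param gap_tol_deg maximum tolerated angular run of rays with no
#'   detectable ridge peak; longer gaps abort with an error naming the gap.
#' @param min_peak_snr a ray peak must exceed the image background by this
#'   many robust standard deviations to count as found.
#' @param smooth_modes optional angular low-pass: keep radial Fourier modes
#'   up to this number, suppressing per-vertex localisation noise (which
#'   otherwise inflates the perimeter and hence the membrane strain).
#'   `NULL` (default) returns the raw ridge positions; the pipeline uses 60,
#'   well above the analysed deformation band (q <= 24).
#' @return a [membrane_contour].
#' @export
extract_contour <- function(membrane_image, pixel_size_um,
                            init = NULL, n_vertices = 360L,
                            search_fraction = 0.45,
                            gap_tol_deg = 25, min_peak_snr = 4,
                            smooth_modes = NULL) {
  img <- membrane_image
  stopifnot(is.matrix(img), pixel_size_um > 0)
  bg <- stats::median(img)
  noise <- stats::mad(img)
  if (noise == 0) noise <- stats::sd(img)
  if (is.null(init)) {
    thr <- bg + max(min_peak_snr * noise, 0.25 * (max(img) - bg))
    mask <- img > thr
    if (!any(mask) || max(img) <= bg + min_peak_snr * noise) {
      stop("no membrane ring found: image has no significant bright structure")
    }
    lab <- EBImage::bwlabel(mask * 1)
    tab <- tabulate(lab[lab > 0])
    keep <- which.max(tab)
    sel <- which(lab == keep, arr.ind = TRUE)
    cx <- (mean(sel[, 2]) - 0.5) * pixel_size_um
    cy <- (mean(sel[, 1]) - 0.5) * pixel_size_um
    r0 <- mean(sqrt(((sel[, 2] - 0.5) * pixel_size_um - cx)^2 +
                      ((sel[, 1] - 0.5) * pixel_size_um - cy)^2))
  } else {
    cx <- init$center_um[1]; cy <- init$center_um[2]; r0 <- init$radius_um
  }
  if (!is.finite(r0) || r0 <= 2 * pixel_size_um) {
    stop("no membrane ring found: initial radius estimate degenerate")
  }

  theta <- seq(-pi, pi, length.out = n_vertices + 1L)[-1L]
  cast <- function(cx, cy, r0) {
    r_lo <- max((1 - search_fraction) * r0, 2 * pixel_size_um)
    r_hi <- (1 + search_fraction) * r0
    rs <- seq(r_lo, r_hi, by = pixel_size_um / 2)
    ct <- cos(theta); st <- sin(theta)
    xq <- outer(ct, rs) + cx          # n_vertices x n_r
    yq <- outer(st, rs) + cy
    rc <- .um_to_rc(xq, yq, pixel_size_um)
    prof <- matrix(bilinear_sample(img, as.vector(rc$row), as.vector(rc$col)),
                   nrow = n_vertices)
    r_peak <- rep(NA_real_, n_vertices)
    for (k in seq_len(n_vertices)) {
      p <- prof[k, ]
      i0 <- which.max(p)
      if (p[i0] < bg + min_peak_snr * noise) next
      ip <- subpixel_peak_1d(p, i0)
      r_peak[k] <- r_lo + (ip - 1) * pixel_size_um / 2
    }
    r_peak
  }

  r_peak <- cast(cx, cy, r0)
  miss <- is.na(r_peak)
  if (all(miss)) stop("no membrane ring found along any ray")
  # longest circular run of missing rays
  if (any(miss)) {
    runs <- rle(c(miss, miss))       # doubled for wrap-around runs
    bad <- max(c(0, runs$lengths[runs$values]))
    bad <- min(bad, n_vertices)
    if (bad * 360 / n_vertices > gap_tol_deg) {
      at <- theta[which(miss)[1]] * 180 / pi
      stop(sprintf(
        "membrane ring broken: %.0f degree gap (tolerance %.0f) near theta = %.0f deg",
        bad * 360 / n_vertices, gap_tol_deg, at
      ))
    }
    r_peak[miss] <- periodic_interp(theta[!miss], r_peak[!miss], theta[miss])
  }
  # re-centre once and re-cast so theta is parameterised about the contour
  cx2 <- mean(cx + r_peak * cos(theta))
  cy2 <- mean(cy + r_peak * sin(theta))
  r_peak2 <- cast(cx2, cy2, mean(r_peak))
  if (mean(is.na(r_peak2)) < 0.05) {
    miss2 <- is.na(r_peak2)
    if (any(miss2)) {
      r_peak2[miss2] <- periodic_interp(theta[!miss2], r_peak2[!miss2],
                                        theta[miss2])
    }
    r_peak <- r_peak2; cx <- cx2; cy <- cy2
  }
  if (!is.null(smooth_modes) && smooth_modes < n_vertices %/% 2) {
    rf <- stats::fft(r_peak)
    keep <- c(seq_len(smooth_modes + 1),
              seq(n_vertices - smooth_modes + 1, n_vertices))
    rf[setdiff(seq_len(n_vertices), keep)] <- 0
    r_peak <- Re(stats::fft(rf, inverse = TRUE)) / n_vertices
  }
  membrane_contour(cx + r_peak * cos(theta), cy + r_peak * sin(theta))
}

#' Radial decomposition of a contour about its centre of mass
#'
#' Represents a star-shaped contour as a radial function \eqn{R(\theta)}
#' sampled on a uniform angular grid over \eqn{(-\pi, \pi]} by periodic
#' linear interpolation of the vertex radii, and returns the deformation
#' amplitude \eqn{u(\theta) = R(\theta) - \langle R \rangle_\theta}.
#'
#' @param contour a [membrane_contour].
#' @param n_theta number of uniform angular samples.
#' @return list with `theta` (radians), `R_um`, `u_um`, `R_mean_um`.
#' @export
radial_decomposition <- function(contour, n_theta = 360L) {
  dx <- contour$x - contour$center["x"]
  dy <- contour$y - contour$center["y"]
  th_v <- atan2(dy, dx)
  r_v <- sqrt(dx^2 + dy^2)
  # star-shape check: for a CCW contour the vertex angles must wind
  # monotonically (every ray from the centre crosses the contour once)
  dth <- wrap_angle(diff(th_v))
  if (any(dth < -1e-9)) {
    bad <- th_v[which(dth < -1e-9)[1]]
    stop(sprintf(
      "contour is not star-shaped about its centre (ray near theta = %.1f deg crosses more than once)",
      bad * 180 / pi
    ))
  }
  theta <- seq(-pi, pi, length.out = n_theta + 1L)[-1L]
  R <- periodic_interp(th_v, r_v, theta)
  R_mean <- mean(R)
  list(theta = theta, R_um = R, u_um = R - R_mean, R_mean_um = R_mean)
}

#' Shape metrics of a membrane contour
#'
#' Circularity \eqn{C = 4\pi A / L^2} (1 for a circle, smaller for deformed
#' shapes), membrane strain \eqn{\epsilon_{memb} = 1 - C}, the mean radius
#' and the maximum radial deformation \eqn{R_{max}/\langle R\rangle}.
#'
#' @param contour a [membrane_contour].
#' @param n_theta angular samples used for the radial quantities.
#' @return list with `circularity`, `eps_memb`, `R_mean_um`, `R_max_um`,
#'   `R_max_ratio`, `area_um2`, `perimeter_um`.
#' @export
shape_metrics <- function(contour, n_theta = 360L) {
  A <- contour$area_um2
  L <- contour$perimeter_um
  if (A <= 0) stop("degenerate contour: non-positive area")
  C <- 4 * pi * A / L^2
  rd <- radial_decomposition(contour, n_theta)
  list(
    circularity = C,
    eps_memb = 1 - C,
    R_mean_um = rd$R_mean_um,
    R_max_um = max(rd$R_um),
    R_max_ratio = max(rd$R_um) / rd$R_mean_um,
    area_um2 = A,
    perimeter_um = L
  )
}

#' Actin polarity from per-vertex intensities
#'
#' The deviation of the actin intensity-weighted membrane position from the
#' liposome centre of mass, normalised by the liposome radius:
#' \eqn{P_{act} = |r_{act} - r_c| / R} with
#' \eqn{r_{act} = \sum_i r_i I_i / \sum_i I_i}.
#'
#' @param contour a [membrane_contour].
#' @param intensity non-negative per-vertex actin intensities.
#' @param R_um normalising radius; defaults to the contour's mean radius
#'   (callers tracking a timelapse should pass the initial-frame radius).
#' @return scalar polarity in \[0, 1\].
#' @export
polarity_from_intensity <- function(contour, intensity, R_um = NULL) {
  stopifnot(length(intensity) == length(contour$x))
  if (all(intensity == 0)) stop("all-zero actin intensity on contour")
  if (any(intensity < 0)) stop("negative actin intensity")
  w <- intensity / sum(intensity)
  xa <- sum(contour$x * w); ya <- sum(contour$y * w)
  if (is.null(R_um)) {
    R_um <- mean(sqrt((contour$x - contour$center["x"])^2 +
                        (contour$y - contour$center["y"])^2))
  }
  unname(sqrt((xa - contour$center["x"])^2 +
                (ya - contour$center["y"])^2) / R_um)
}

#' Actin polarity sampled from the actin-channel image
#'
#' Samples the cortical actin intensity at each contour vertex as the mean
#' intensity in a narrow band along the inward normal (the cortex is
#' sub-resolution thick, so a narrow band avoids the volume signal), then
#' computes [polarity_from_intensity].
#'
#' @param contour a [membrane_contour].
#' @param actin_image numeric matrix, actin channel aligned with the
#'   membrane channel.
#' @param pixel_size_um pixel size in µm.
#' @param band_px half-width of the sampling band in pixels (default 3).
#' @param R_um normalising radius (initial-frame mean radius); defaults to
#'   this contour's mean radius.
#' @param background `"plateau"` (default) subtracts, at each vertex, the
#'   mean of two reference bands taken just inside (volume plateau) and
#'   just outside (exterior plateau) the cortex, so the polarity reflects
#'   the cortical signal above background rather than the volume signal;
#'   `"none"` uses raw band intensities.
#' @return scalar polarity in \[0, 1\].
#' @export
actin_polarity <- function(contour, actin_image, pixel_size_um,
                           band_px = 3, R_um = NULL,
                           background = c("plateau", "none")) {
  background <- match.arg(background)
  n <- length(contour$x)
  # inward unit normal from the local tangent, oriented toward the centre
  xm <- c(contour$x[n], contour$x[-n]); xp <- c(contour$x[-1], contour$x[1])
  ym <- c(contour$y[n], contour$y[-n]); yp <- c(contour$y[-1], contour$y[1])
  tx <- xp - xm; ty <- yp - ym
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  to_c_x <- contour$center["x"] - contour$x
  to_c_y <- contour$center["y"] - contour$y
  flip <- (nx * to_c_x + ny * to_c_y) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  s <- seq(-band_px, band_px, by = 0.5) * pixel_size_um
  d_ref <- band_px * pixel_size_um + 0.6    # reference band centre offset, um
  I <- numeric(n)
  for (k in seq_len(n)) {
    rc <- .um_to_rc(contour$x[k] + s * nx[k], contour$y[k] + s * ny[k],
                    pixel_size_um)
    I[k] <- mean(bilinear_sample(actin_image, rc$row, rc$col))
    if (background == "plateau") {
      rc_in <- .um_to_rc(contour$x[k] + (s + d_ref) * nx[k],
                         contour$y[k] + (s + d_ref) * ny[k], pixel_size_um)
      rc_out <- .um_to_rc(contour$x[k] + (s - d_ref) * nx[k],
                          contour$y[k] + (s - d_ref) * ny[k], pixel_size_um)
      bg <- 0.5 * (mean(bilinear_sample(actin_image, rc_in$row, rc_in$col)) +
                     mean(bilinear_sample(actin_image, rc_out$row, rc_out$col)))
      I[k] <- max(I[k] - bg, 0)
    }
  }
  if (all(I == 0)) stop("all-zero actin intensity along contour band")
  polarity_from_intensity(contour, I, R_um = R_um)
}

#' Per-frame shape metrics and their maxima over a timelapse
#'
#' Runs [shape_metrics] and (when the actin stack is given) [actin_polarity]
#' on every frame and reports the maxima of the membrane strain and actin
#' polarity over the observation window.  The polarity normalising radius is
#' fixed to the initial-frame mean radius.
#'
#' @param contours list of [membrane_contour], time-ordered.
#' @param actin_stack optional list of actin-channel matrices, same length.
#' @param pixel_size_um pixel size in µm (needed with `actin_stack`).
#' @param frame_interval_s frame interval in seconds.
#' @param baseline_frame optional frame index whose metrics are subtracted
#'   from the reported strain/polarity series (pre-activation baseline);
#'   `NULL` (default) reports raw values.
#' @param band_px passed to [actin_polarity].
#' @return a data.frame with one row per frame (`frame`, `t_s`,
#'   `circularity`, `eps_memb`, `P_act`, `R_mean_um`, `R_max_ratio`) and
#'   attributes `eps_memb_max`, `P_act_max`.
#' @export
metric_timeseries <- function(contours, actin_stack = NULL,
                              pixel_size_um = NULL, frame_interval_s = 6,
                              baseline_frame = NULL, band_px = 3) {
  stopifnot(length(contours) >= 2)
  if (!is.null(actin_stack)) {
    stopifnot(length(actin_stack) == length(contours), !is.null(pixel_size_um))
  }
  n <- length(contours)
  R0 <- radial_decomposition(contours[[1]])$R_mean_um
  rows <- lapply(seq_len(n), function(i) {
    m <- shape_metrics(contours[[i]])
    p <- if (!is.null(actin_stack)) {
      actin_polarity(contours[[i]], actin_stack[[i]], pixel_size_um,
                     band_px = band_px, R_um = R0)
    } else NA_real_
    data.frame(
      frame = i, t_s = (i - 1) * frame_interval_s,
      circularity = m$circularity, eps_memb = m$eps_memb, P_act = p,
      R_mean_um = m$R_mean_um, R_max_ratio = m$R_max_ratio
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(baseline_frame)) {
    out$eps_memb <- out$eps_memb - out$eps_memb[baseline_frame]
    if (!all(is.na(out$P_act))) {
      out$P_act <- out$P_act - out$P_act[baseline_frame]
    }
  }
  attr(out, "eps_memb_max") <- max(out$eps_memb)
  attr(out, "P_act_max") <- if (all(is.na(out$P_act))) NA_real_ else
    max(out$P_act, na.rm = TRUE)
  out
}
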