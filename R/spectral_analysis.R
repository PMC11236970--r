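#' Angular power spectrum of the membrane deformation amplitude
#'
#' Computes the squared Fourier transform of \eqn{u(\theta, t)} per frame
#' and averages over frames.  The one-sided spectrum is normalised as
#' \eqn{P(q) = 2 |U_q|^2 / N} (with the Nyquist term counted once), so that
#' Parseval holds in the form \eqn{\sum_{q \ge 1} P(q) = N \,
#' \mathrm{var}_\theta(u)} for zero-mean u on an N-point grid.  Only the
#' relative q-dependence matters for scaling-exponent analysis.
#'
#' @param u either a numeric matrix (frames in rows, uniform theta samples
#'   in columns) or a list of numeric vectors, one per frame.
#' @param frames optional integer vector selecting which frames to average
#'   (default: all; timelapse analyses conventionally average the first 20
#'   post-activation frames).
#' @param theta optional angular grid; if supplied it must be uniform.
#' @return object of class `deformation_spectrum`: list with `q` (1..N/2),
#'   `power`, `n_frames_averaged`.
#' @export
deformation_power_spectrum <- function(u, frames = NULL, theta = NULL) {
  if (is.list(u) && !is.data.frame(u)) u <- do.call(rbind, u)
  if (is.vector(u)) u <- matrix(u, nrow = 1)
  if (!is.null(theta)) {
    d <- diff(theta)
    if (max(abs(d - d[1])) > 1e-8 * abs(d[1])) {
      stop("theta grid is not uniform: resample u before computing the spectrum")
    }
  }
  if (!is.null(frames)) u <- u[frames, , drop = FALSE]
  stopifnot(nrow(u) >= 1)
  N <- ncol(u)
  qmax <- N %/% 2
  pw <- matrix(0, nrow(u), qmax)
  for (f in seq_len(nrow(u))) {
    U <- stats::fft(u[f, ])
    p <- Mod(U[2:(qmax + 1)])^2 * 2 / N
    if (N %% 2 == 0) p[qmax] <- p[qmax] / 2   # Nyquist counted once
    pw[f, ] <- p
  }
  structure(
    list(q = seq_len(qmax), power = colMeans(pw),
         n_frames_averaged = nrow(u)),
    class = "deformation_spectrum"
  )
}

#' Scaling exponent of a deformation power spectrum
#'
#' Least-squares slope of log power versus log q; the exponent alpha of the
#' \eqn{q^{-\alpha}} fit is minus the slope.  Modes q = 0, 1 are excluded by
#' default (area/translation artefacts removed at decomposition); zero-power
#' entries are excluded with a warning.
#'
#' @param spectrum a `deformation_spectrum` (or list with `q`, `power`).
#' @param q_range optional `c(qmin, qmax)`; default all q >= 2 (callers
#'   should cap `qmax` at the highest physically meaningful mode, e.g. the
#'   mode content of the scene or the contour noise floor).
#' @return scalar alpha.
#' @export
fit_scaling_exponent <- function(spectrum, q_range = NULL) {
  q <- spectrum$q; p <- spectrum$power
  keep <- q >= 2
  if (!is.null(q_range)) keep <- keep & q >= q_range[1] & q <= q_range[2]
  if (any(p[keep] <= 0)) {
    warning("zero-power modes excluded from the scaling fit")
    keep <- keep & p > 0
  }
  if (sum(keep) < 4) stop("need >= 4 positive-power modes for the scaling fit")
  fit <- stats::lm(log(p[keep]) ~ log(q[keep]))
  -unname(stats::coef(fit)[2])
}

#' Helfrich-form fit of a deformation power spectrum
#'
#' Nonlinear least squares of \eqn{P(q) = 1 / (\kappa' q^4 + \gamma' q^2)}
#' in log space with non-negativity constraints.  The overall amplitude is
#' absorbed into the fitted coefficients (only a two-parameter family is
#' identifiable), so `kappa_fit` and `gamma_fit` are in arbitrary inverse
#' power units; their ratio \eqn{\gamma'/\kappa'} (the squared crossover
#' mode) is scale-invariant.  When one parameter is pinned at the zero bound
#' the fit is flagged degenerate.
#'
#' @param spectrum a `deformation_spectrum`.
#' @param q_min lowest mode used (default 2).
#' @param q_max highest mode used (default all).
#' @return list with `kappa_fit`, `gamma_fit`, `crossover_q`
#'   (\eqn{\sqrt{\gamma'/\kappa'}}, NA when degenerate), `degenerate`
#'   (`"none"`, `"kappa_only"` or `"gamma_only"`), `residual_rms`.
#' @export
fit_fluctuation_model <- function(spectrum, q_min = 2, q_max = Inf) {
  q <- spectrum$q; p <- spectrum$power
  keep <- q >= q_min & q <= q_max & p > 0
  if (sum(keep) < 5) stop("need >= 5 positive-power modes for the Helfrich fit")
  q <- q[keep]; p <- p[keep]
  lp <- log(p)
  obj <- function(par) {
    den <- par[1] * q^4 + par[2] * q^2
    if (any(den <= 0)) return(1e10)
    sum((lp - log(1 / den))^2)
  }
  # initialise from the pure-q^-4 and pure-q^-2 one-parameter solutions
  k0 <- exp(mean(-lp - 4 * log(q)))
  g0 <- exp(mean(-lp - 2 * log(q)))
  starts <- list(c(k0, g0 / 10), c(k0 / 10, g0), c(k0, 0), c(0, g0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(pmax(s, 0), obj, method = "L-BFGS-B",
                      lower = c(0, 0),
                      control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value)) {
    stop("Helfrich fit did not converge; residuals non-finite")
  }
  kap <- best$par[1]; gam <- best$par[2]
  tiny_k <- kap * max(q)^4 < 1e-6 * gam * max(q)^2
  tiny_g <- gam * min(q)^2 < 1e-6 * kap * min(q)^4
  degenerate <- if (tiny_k) "gamma_only" else if (tiny_g) "kappa_only" else "none"
  list(
    kappa_fit = kap, gamma_fit = gam,
    crossover_q = if (degenerate == "none") sqrt(gam / kap) else NA_real_,
    degenerate = degenerate,
    residual_rms = sqrt(best$value / length(q))
  )
}

#' Circular autocorrelation of u(theta) and the deformation size
#'
#' Computes the wrap-around angular autocorrelation
#' \eqn{\langle u(\theta + \Delta\theta) u(\theta)\rangle_\theta} per frame,
#' finds each frame's first zero crossing (sign change, refined by linear
#' interpolation), and reports the characteristic deformation size
#' \eqn{\theta_c} as the minimum first zero over frames together with the
#' frame t' at which it occurs.  Normalisation by the variance does not move
#' the zero crossing; the normalised ACF is returned.
#'
#' @param u matrix (frames x uniform theta samples) or list of vectors.
#' @return object of class `deformation_size`: list with `theta_c_deg`,
#'   `t_prime` (frame index), `first_zero_deg` (per frame, NA when the ACF
#'   has no zero crossing), `acf` (frames x lags, normalised), `lag_deg`.
#' @export
angular_autocorrelation_size <- function(u) {
  if (is.list(u) && !is.data.frame(u)) u <- do.call(rbind, u)
  if (is.vector(u)) u <- matrix(u, nrow = 1)
  N <- ncol(u)
  nlag <- N %/% 2
  lag_deg <- (0:nlag) * 360 / N
  acfs <- matrix(NA_real_, nrow(u), nlag + 1)
  fz <- rep(NA_real_, nrow(u))
  for (f in seq_len(nrow(u))) {
    v <- u[f, ] - mean(u[f, ])
    a <- Re(stats::fft(Mod(stats::fft(v))^2, inverse = TRUE)) / N^2
    a <- a[1:(nlag + 1)]
    if (a[1] <= 0) next
    acfs[f, ] <- a / a[1]
    sg <- which(a[-1] * a[-length(a)] <= 0 & a[-length(a)] > 0)
    if (length(sg)) {
      i <- sg[1]   # linear interpolation between lags i-1 and i (0-based)
      frac <- a[i] / (a[i] - a[i + 1])
      fz[f] <- (i - 1 + frac) * 360 / N
    }
  }
  if (all(is.na(fz))) {
    stop("no frame has an autocorrelation zero crossing; deformation size undefined")
  }
  t_prime <- which.min(fz)
  structure(
    list(theta_c_deg = fz[t_prime], t_prime = t_prime,
         first_zero_deg = fz, acf = acfs, lag_deg = lag_deg),
    class = "deformation_size"
  )
}

# Pratt algebraic circle fit: returns list(center = c(x, y), radius);
# radius = Inf for (near-)collinear points.
pratt_circle <- function(x, y) {
  z <- x^2 + y^2
  M <- cbind(z, x, y, 1)
  P <- crossprod(M)                      # 4x4 moment matrix
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(solve(B, P))
  # smallest non-negative eigenvalue's eigenvector (Pratt constraint)
  lam <- Re(ev$values); vec <- Re(ev$vectors)
  ok <- which(lam > -1e-8 * max(abs(lam)))
  if (!length(ok)) return(list(center = c(NA, NA), radius = Inf))
  i <- ok[which.min(lam[ok])]
  A <- vec[1, i]; Bc <- vec[2, i]; Cc <- vec[3, i]; D <- vec[4, i]
  if (abs(A) < 1e-12 * max(abs(c(Bc, Cc)))) {
    return(list(center = c(NA, NA), radius = Inf))
  }
  cx <- -Bc / (2 * A); cy <- -Cc / (2 * A)
  r2 <- (Bc^2 + Cc^2 - 4 * A * D) / (4 * A^2)
  list(center = c(cx, cy), radius = if (r2 > 0) sqrt(r2) else Inf)
}

#' Signed local curvature along a closed contour
#'
#' At each vertex a circle is fitted (Pratt algebraic fit) through the
#' vertex and its two neighbours `separation` vertices away; the signed
#' curvature is \eqn{\pm 1/r_{fit}} with the sign from the local turning
#' direction (positive for the convex, counter-clockwise sense).  Collinear
#' triplets give curvature 0 and are flagged.
#'
#' @param contour a [membrane_contour] (or an open curve given as a list
#'   with `x`, `y`, in which case set `closed = FALSE`).
#' @param separation vertex separation of the fitted triplet (default 5).
#' @param closed treat the vertex list as a closed polygon (default TRUE).
#' @return object of class `curvature_profile`: list with `curvature_per_um`
#'   (per vertex; NA at the unfittable ends of an open curve), `flagged`
#'   (logical, collinear triplets), `ds_um` (arc length per vertex),
#'   `total_turning` (\eqn{\sum \kappa\, ds}, 2 pi for a simple closed CCW
#'   contour).
#' @export
local_curvature <- function(contour, separation = 5L, closed = TRUE) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  stopifnot(separation >= 1, n > 2 * separation)
  idx <- function(i) ((i - 1) %% n) + 1
  kappa <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  rng <- if (closed) seq_len(n) else (separation + 1):(n - separation)
  for (i in rng) {
    im <- idx(i - separation); ip <- idx(i + separation)
    if (!closed && (i - separation < 1 || i + separation > n)) next
    fit <- pratt_circle(c(x[im], x[i], x[ip]), c(y[im], y[i], y[ip]))
    crossp <- (x[i] - x[im]) * (y[ip] - y[i]) - (y[i] - y[im]) * (x[ip] - x[i])
    seg2 <- sqrt(((x[i] - x[im])^2 + (y[i] - y[im])^2) *
                   ((x[ip] - x[i])^2 + (y[ip] - y[i])^2))
    if (!is.finite(fit$radius) || abs(crossp) < 1e-10 * seg2) {
      kappa[i] <- 0; flagged[i] <- TRUE   # collinear: infinite radius
      next
    }
    kappa[i] <- sign(crossp) / fit$radius
  }
  xm <- x[idx(seq_len(n) - 1)]; ym <- y[idx(seq_len(n) - 1)]
  xp <- x[idx(seq_len(n) + 1)]; yp <- y[idx(seq_len(n) + 1)]
  ds <- 0.5 * (sqrt((x - xm)^2 + (y - ym)^2) + sqrt((xp - x)^2 + (yp - y)^2))
  structure(
    list(curvature_per_um = kappa, flagged = flagged, ds_um = ds,
         total_turning = sum(kappa * ds, na.rm = TRUE),
         separation = separation),
    class = "curvature_profile"
  )
}
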