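# Multi-pass windowed normalized cross-correlation PIV, cumulative
# compressive strain and cortical flow speed.

# 2D integral-image local sums of m over w x w windows; returns matrix of
# size (nrow-w+1) x (ncol-w+1), entry [i,j] = sum(m[i:(i+w-1), j:(j+w-1)]).
.window_sums <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)   # transposed cumsum2d
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  nr <- nrow(m); nc <- ncol(m)
  i <- seq_len(nr - w + 1); j <- seq_len(nc - w + 1)
  cs[i + w, j + w, drop = FALSE] - cs[i, j + w, drop = FALSE] -
    cs[i + w, j, drop = FALSE] + cs[i, j, drop = FALSE]
}

# Normalized cross-correlation of interrogation window a (iw x iw) against
# search window b (sw x sw).  Returns the (sw-iw+1)^2 NCC map, or NULL for a
# featureless interrogation window.
.ncc_map <- function(a, b) {
  iw <- nrow(a); sw <- nrow(b)
  a0 <- a - mean(a)
  na <- sqrt(sum(a0^2))
  if (na < 1e-12) return(NULL)
  A <- matrix(0, sw, sw)
  A[1:iw, 1:iw] <- a0
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(b), inverse = TRUE)) /
    (sw * sw)
  nvalid <- sw - iw + 1
  C <- C[1:nvalid, 1:nvalid, drop = FALSE]
  S1 <- .window_sums(b, iw)
  S2 <- .window_sums(b^2, iw)
  denom <- na * sqrt(pmax(S2 - S1^2 / (iw * iw), 0))
  ncc <- C / denom
  ncc[denom < 1e-8 * na] <- NA
  ncc
}

# iterative neighbour-mean fill of NA entries (used to seed finer passes and
# for divergence differencing; never for reported vectors)
.fill_na_neighbours <- function(m, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    nas <- which(is.na(m), arr.ind = TRUE)
    if (nrow(nas) == 0) return(m)
    filled <- m
    for (k in seq_len(nrow(nas))) {
      r <- nas[k, 1]; c <- nas[k, 2]
      nb <- c(
        if (r > 1) m[r - 1, c], if (r < nrow(m)) m[r + 1, c],
        if (c > 1) m[r, c - 1], if (c < ncol(m)) m[r, c + 1]
      )
      if (any(!is.na(nb))) filled[r, c] <- mean(nb, na.rm = TRUE)
    }
    if (identical(filled, m)) return(filled)   # isolated: nothing reachable
    m <- filled
  }
  m
}

#' Default PIV quality-filter parameters
#'
#' Nominal defaults: minimum normalized correlation 0.6, peak-noise
#' criterion 0.20 (a vector is rejected when the secondary correlation peak
#' comes within 20% of the primary), and a neighbourhood-median outlier
#' threshold of 5 robust residuals.
#'
#' @param corr_min minimum NCC peak value.
#' @param noise secondary/primary peak closeness criterion in (0, 1).
#' @param threshold normalized-median outlier threshold (px residual units).
#' @param eps_px stabilising constant of the median test (px).
#' @return list of quality parameters.
#' @export
piv_quality <- function(corr_min = 0.6, noise = 0.20, threshold = 5,
                        eps_px = 0.2) {
  list(corr_min = corr_min, noise = noise, threshold = threshold,
       eps_px = eps_px)
}

#' Multi-pass cross-correlation PIV between two frames
#'
#' Estimates the displacement field from `frame_a` to `frame_b` by
#' normalized cross-correlation of interrogation windows within larger
#' search windows, in a cascade of decreasing window sizes: each coarse
#' pass seeds the search-window offsets of the next finer pass.  Peaks are
#' localised to sub-pixel precision by three-point Gaussian interpolation.
#' Vectors failing the quality filter (low correlation, ambiguous secondary
#' peak, or neighbourhood-median outliers) are marked invalid, never zero.
#'
#' @param frame_a,frame_b numeric matrices of identical shape.
#' @param window_cascade list of `c(interrogation, search)` pixel sizes with
#'   strictly decreasing interrogation sizes.  The defaults follow common
#'   practice for these data: 100/200, 60/120, 48/96 px (use a final pass of
#'   16 or 32 px for cortical flow analysis).
#' @param quality a [piv_quality] list.
#' @param pixel_size_um pixel size for the physical units of the output.
#' @param dt_s frame interval (s), recorded in the result.
#' @return object of class `displacement_field`: list with `x_um`, `y_um`
#'   (grid node coordinates), `u_um`, `v_um` (displacement matrices, rows
#'   indexed by y), `u_px`, `v_px`, `quality` (peak NCC), `valid`,
#'   `window_cascade`, `pixel_size_um`, `dt_s`.
#' @export
piv_displacement <- function(frame_a, frame_b,
                             window_cascade = list(c(100, 200), c(60, 120),
                                                   c(48, 96)),
                             quality = piv_quality(),
                             pixel_size_um = 1, dt_s = 1) {
  stopifnot(identical(dim(frame_a), dim(frame_b)))
  iws <- vapply(window_cascade, `[`, numeric(1), 1)
  if (any(diff(iws) >= 0)) {
    stop("window cascade must have strictly decreasing interrogation sizes")
  }
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  prev <- NULL
  for (p in seq_along(window_cascade)) {
    iw <- window_cascade[[p]][1]
    sw <- window_cascade[[p]][2]
    if (sw <= iw) stop("search window must exceed interrogation window")
    half_i <- iw %/% 2; half_s <- sw %/% 2
    spacing <- max(iw %/% 2, 4L)
    rows <- seq(half_s + 1L, nr - half_s, by = spacing)
    cols <- seq(half_s + 1L, nc - half_s, by = spacing)
    if (!length(rows) || !length(cols)) {
      stop(sprintf("image too small for a %d px search window", sw))
    }
    u <- matrix(NA_real_, length(rows), length(cols))   # x-displacement, px
    v <- matrix(NA_real_, length(rows), length(cols))   # y-displacement, px
    qual <- matrix(NA_real_, length(rows), length(cols))
    noise_ratio <- matrix(NA_real_, length(rows), length(cols))
    # seed from previous pass (invalids filled for seeding only)
    if (!is.null(prev)) {
      pu <- .fill_na_neighbours(ifelse(prev$valid, prev$u, NA))
      pv <- .fill_na_neighbours(ifelse(prev$valid, prev$v, NA))
      pu[is.na(pu)] <- 0; pv[is.na(pv)] <- 0
      seed_u <- pracma::interp2(prev$cols, prev$rows, pu,
                                pmin(pmax(rep(cols, each = length(rows)),
                                          min(prev$cols)), max(prev$cols)),
                                pmin(pmax(rep(rows, length(cols)),
                                          min(prev$rows)), max(prev$rows)))
      seed_v <- pracma::interp2(prev$cols, prev$rows, pv,
                                pmin(pmax(rep(cols, each = length(rows)),
                                          min(prev$cols)), max(prev$cols)),
                                pmin(pmax(rep(rows, length(cols)),
                                          min(prev$rows)), max(prev$rows)))
      seed_u <- matrix(seed_u, length(rows), length(cols))
      seed_v <- matrix(seed_v, length(rows), length(cols))
    } else {
      seed_u <- matrix(0, length(rows), length(cols))
      seed_v <- matrix(0, length(rows), length(cols))
    }
    for (ri in seq_along(rows)) {
      for (ci in seq_along(cols)) {
        r0 <- rows[ri]; c0 <- cols[ci]
        su <- round(seed_u[ri, ci]); sv <- round(seed_v[ri, ci])
        a_r <- (r0 - half_i):(r0 + half_i - 1L)
        a_c <- (c0 - half_i):(c0 + half_i - 1L)
        b_r <- (r0 + sv - half_s):(r0 + sv + half_s - 1L)
        b_c <- (c0 + su - half_s):(c0 + su + half_s - 1L)
        if (min(b_r) < 1 || max(b_r) > nr || min(b_c) < 1 || max(b_c) > nc) {
          next
        }
        ncc <- .ncc_map(frame_a[a_r, a_c], frame_b[b_r, b_c])
        if (is.null(ncc) || all(is.na(ncc))) next   # featureless: invalid
        pk <- which(ncc == max(ncc, na.rm = TRUE), arr.ind = TRUE)[1, ]
        pval <- ncc[pk[1], pk[2]]
        # secondary peak outside the 3x3 neighbourhood of the primary
        masked <- ncc
        mr <- max(1, pk[1] - 1):min(nrow(ncc), pk[1] + 1)
        mc <- max(1, pk[2] - 1):min(ncol(ncc), pk[2] + 1)
        masked[mr, mc] <- NA
        p2 <- if (all(is.na(masked))) -Inf else max(masked, na.rm = TRUE)
        # sub-pixel peak along each axis
        dr <- subpixel_peak_1d(ncc[, pk[2]], pk[1]) - pk[1]
        dc <- subpixel_peak_1d(ncc[pk[1], ], pk[2]) - pk[2]
        off0 <- (nrow(ncc) - 1) / 2   # zero-displacement offset index
        v[ri, ci] <- sv + (pk[1] - 1 + dr) - off0
        u[ri, ci] <- su + (pk[2] - 1 + dc) - off0
        qual[ri, ci] <- pval
        noise_ratio[ri, ci] <- if (is.finite(p2) && pval > 0) p2 / pval else 0
      }
    }
    valid <- !is.na(u) & qual >= quality$corr_min &
      noise_ratio <= (1 - quality$noise)
    valid[is.na(valid)] <- FALSE
    prev <- list(rows = rows, cols = cols, u = u, v = v, qual = qual,
                 valid = valid)
  }
  # neighbourhood-median outlier rejection on the final pass
  u <- prev$u; v <- prev$v; valid <- prev$valid
  med_res <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) {
      for (c in seq_len(ncol(m))) {
        if (!valid[r, c]) next
        rr <- max(1, r - 1):min(nrow(m), r + 1)
        cc <- max(1, c - 1):min(ncol(m), c + 1)
        nb <- m[rr, cc][valid[rr, cc]]
        nb <- nb[-match(m[r, c], nb)]
        if (length(nb) < 3) next
        md <- stats::median(nb)
        sc <- stats::median(abs(nb - md)) + quality$eps_px
        if (abs(m[r, c] - md) / sc > quality$threshold) out[r, c] <- TRUE
      }
    }
    out
  }
  outlier <- med_res(u) | med_res(v)
  valid[outlier] <- FALSE
  u[!valid] <- NA; v[!valid] <- NA
  structure(
    list(
      x_um = (prev$cols - 0.5) * pixel_size_um,
      y_um = (prev$rows - 0.5) * pixel_size_um,
      u_um = u * pixel_size_um, v_um = v * pixel_size_um,
      u_px = u, v_px = v,
      quality = prev$qual, valid = valid,
      window_cascade = window_cascade,
      pixel_size_um = pixel_size_um, dt_s = dt_s
    ),
    class = "displacement_field"
  )
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d x %d grid, %.0f%% valid vectors\n",
    length(x$y_um), length(x$x_um), 100 * mean(x$valid)
  ))
  invisible(x)
}

#' Discrete divergence of a displacement field
#'
#' Central differences of (u, v) on the PIV grid.  Invalid vectors are
#' interpolated from their neighbours for the differencing only (so strain
#' integration is not biased by dropouts); the returned `defined` mask marks
#' interior nodes where the divergence could be evaluated.
#'
#' The default method fits a local least-squares plane to each velocity
#' component over the surrounding `(2w+1) x (2w+1)` node neighbourhood and
#' sums the fitted slopes.  The plane fit is exact for affine flows (on any
#' neighbourhood, including the asymmetric ones at grid edges) while
#' pooling the sub-pixel correlation noise that raw differencing would
#' amplify; on symmetric neighbourhoods it is also exact for quadratic
#' fields, so convergence remains second order.  `method = "central"` gives
#' plain central differences.
#'
#' @param field a `displacement_field`.
#' @param method `"plane_fit"` (default) or `"central"`.
#' @param fit_halfwidth neighbourhood half-width w for the plane fit.
#' @return list with `div` (dimensionless, per displacement step),
#'   `defined` logical matrix.
#' @export
divergence_field <- function(field, method = c("plane_fit", "central"),
                             fit_halfwidth = 1L) {
  method <- match.arg(method)
  u <- .fill_na_neighbours(field$u_um)
  v <- .fill_na_neighbours(field$v_um)
  ny <- length(field$y_um); nx <- length(field$x_um)
  if (ny < 3 || nx < 3) {
    stop("PIV grid too coarse for divergence (< 3 nodes across)")
  }
  dx <- mean(diff(field$x_um)); dy <- mean(diff(field$y_um))
  div <- matrix(NA_real_, ny, nx)
  if (method == "central") {
    div[2:(ny - 1), 2:(nx - 1)] <-
      (u[2:(ny - 1), 3:nx] - u[2:(ny - 1), 1:(nx - 2)]) / (2 * dx) +
      (v[3:ny, 2:(nx - 1)] - v[1:(ny - 2), 2:(nx - 1)]) / (2 * dy)
    return(list(div = div, defined = !is.na(div)))
  }
  w <- max(1L, as.integer(fit_halfwidth))
  for (r in 2:(ny - 1)) {
    rr <- max(1, r - w):min(ny, r + w)
    for (c in 2:(nx - 1)) {
      cc <- max(1, c - w):min(nx, c + w)
      X <- cbind(1, rep(field$x_um[cc], each = length(rr)) - field$x_um[c],
                 rep(field$y_um[rr], times = length(cc)) - field$y_um[r])
      uu <- as.vector(u[rr, cc]); vv <- as.vector(v[rr, cc])
      ok <- !is.na(uu) & !is.na(vv)
      if (sum(ok) < 4) next
      cf_u <- stats::.lm.fit(X[ok, , drop = FALSE], uu[ok])$coefficients
      cf_v <- stats::.lm.fit(X[ok, , drop = FALSE], vv[ok])$coefficients
      div[r, c] <- cf_u[2] + cf_v[3]
    }
  }
  list(div = div, defined = !is.na(div))
}

#' Cumulative compressive strain of the actin network
#'
#' Integrates the negative part of the divergence of the per-frame-pair
#' displacement fields over the liposome interior:
#' \deqn{\epsilon(t) = -\sum_{t' \le t} \frac{\int_{mask} \min(\nabla\cdot
#' u(r, t'), 0)\, dA}{\int_{mask} dA}.}
#' Positive (expansive) divergence is clipped to zero before integrating,
#' keeping the compressive strain non-decreasing under expansion noise.
#' The strain rate is the forward difference of epsilon over the frame
#' interval.
#'
#' @param fields list of `displacement_field`, time-ordered, common grid.
#' @param mask region of integration: a logical matrix on the PIV grid or a
#'   [membrane_contour] (interior taken).
#' @param dt_s frame interval (s).
#' @return data.frame of class `strain_series` with `t_s`, `epsilon`,
#'   `rate_per_s`; `epsilon[1] = 0` at t = 0.
#' @export
cumulative_compressive_strain <- function(fields, mask, dt_s = 6) {
  stopifnot(length(fields) >= 1)
  f1 <- fields[[1]]
  if (inherits(mask, "membrane_contour")) {
    G <- expand.grid(y = f1$y_um, x = f1$x_um)
    inside <- pracma::inpolygon(G$x, G$y, mask$x, mask$y)
    mask <- matrix(inside, length(f1$y_um), length(f1$x_um))
  }
  stopifnot(is.logical(mask),
            all(dim(mask) == c(length(f1$y_um), length(f1$x_um))))
  if (!any(mask)) stop("empty integration mask")
  # require >= 3 nodes across the mask in both directions
  if (max(rowSums(mask)) < 3 || max(colSums(mask)) < 3) {
    stop("PIV grid too coarse across the mask (< 3 nodes)")
  }
  eps_step <- vapply(fields, function(f) {
    d <- divergence_field(f)
    use <- mask & d$defined
    if (!any(use)) return(0)
    -mean(pmin(d$div[use], 0))
  }, numeric(1))
  epsilon <- c(0, cumsum(eps_step))
  t_s <- (0:length(fields)) * dt_s
  rate <- c(diff(epsilon) / dt_s, NA)
  structure(
    data.frame(t_s = t_s, epsilon = epsilon, rate_per_s = rate),
    class = c("strain_series", "data.frame")
  )
}

#' Cortical flow speed from displacement fields near the membrane
#'
#' Averages displacement vectors in a band just inside the membrane contour
#' and reports the mean speed in µm/min together with the mean tangential
#' and normal components (signs: tangential positive counter-clockwise,
#' normal positive outward).
#'
#' @param fields list of `displacement_field` (per frame pair).
#' @param contours a single [membrane_contour] or a list matching `fields`.
#' @param band_width_um width of the cortical band inside the contour; must
#'   be at least one PIV grid spacing.
#' @return list with `speed_um_per_min`, `tangential_um_per_min`,
#'   `normal_um_per_min`, `n_vectors`.
#' @export
cortical_flow_speed <- function(fields, contours, band_width_um = 3) {
  if (inherits(contours, "membrane_contour")) {
    contours <- rep(list(contours), length(fields))
  }
  stopifnot(length(contours) == length(fields))
  spacing <- mean(diff(fields[[1]]$x_um))
  if (band_width_um < spacing) {
    stop(sprintf(
      "band width %.2f um below one PIV grid spacing (%.2f um): widen the band or use a smaller final window",
      band_width_um, spacing
    ))
  }
  sp <- c(); tg <- c(); nm <- c()
  for (i in seq_along(fields)) {
    f <- fields[[i]]; ct <- contours[[i]]
    cx <- unname(ct$center["x"]); cy <- unname(ct$center["y"])
    th_v <- atan2(ct$y - cy, ct$x - cx)
    r_v <- sqrt((ct$x - cx)^2 + (ct$y - cy)^2)
    G <- expand.grid(y = f$y_um, x = f$x_um)
    gr <- sqrt((G$x - cx)^2 + (G$y - cy)^2)
    gth <- atan2(G$y - cy, G$x - cx)
    Rg <- periodic_interp(th_v, r_v, gth)
    in_band <- gr <= Rg & gr >= Rg - band_width_um
    ok <- in_band & as.vector(f$valid)
    if (!any(ok)) next
    uu <- as.vector(f$u_um)[ok]; vv <- as.vector(f$v_um)[ok]
    rx <- ((G$x - cx) / pmax(gr, 1e-9))[ok]
    ry <- ((G$y - cy) / pmax(gr, 1e-9))[ok]
    tx <- -ry; ty <- rx                       # CCW tangential unit
    per_min <- 60 / f$dt_s
    sp <- c(sp, sqrt(uu^2 + vv^2) * per_min)
    tg <- c(tg, (uu * tx + vv * ty) * per_min)
    nm <- c(nm, (uu * rx + vv * ry) * per_min)
  }
  if (!length(sp)) {
    stop("no valid vectors in the cortical band: widen the band or use a smaller final PIV window")
  }
  list(
    speed_um_per_min = mean(sp),
    tangential_um_per_min = mean(tg),
    normal_um_per_min = mean(nm),
    n_vectors = length(sp)
  )
}
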