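# Sub-resolution cortex thickness from two-peak radial intensity profiles.

# Gaussian sub-pixel refinement of a peak on a profile sampled at spacing ds
# (positions s); returns the refined peak position or NA.
.refine_peak <- function(s, I, window = 3L) {
  i0 <- which.max(I)
  if (i0 <= window || i0 > length(I) - window) return(NA_real_)
  ip <- subpixel_peak_1d(I, i0)
  s[1] + (ip - 1) * (s[2] - s[1])
}

#' Averaged membrane/actin intensity profiles along inward normals
#'
#' Casts rays along the inward normal at `n_rays` contour vertices, samples
#' both channels by bilinear interpolation, aligns each ray at its membrane
#' peak (sub-pixel Gaussian fit) and averages.  The signed coordinate `s`
#' increases inward and is zero at the membrane peak.  The cortex peak
#' distance Delta, the cortex peak intensity `I_S`, the interior (volume)
#' plateau `I_V` and the exterior plateau `I_out` are estimated from the
#' averaged actin profile (plateaus as medians of the profile tails).
#'
#' @param contour a [membrane_contour].
#' @param membrane_image,actin_image aligned channel matrices.
#' @param pixel_size_um pixel size (µm).
#' @param depth_um profile half-depth on both sides of the membrane (µm);
#'   must cover at least 3 PSF widths.
#' @param n_rays number of rays (evenly spaced vertices).
#' @param step_um sampling step along the ray (default half a pixel).
#' @return object of class `radial_profile`: list with `s_um`, `I_memb`,
#'   `I_act`, `delta_um`, `I_S`, `I_V`, `I_out`, `n_rays_used`.
#' @export
normal_intensity_profiles <- function(contour, membrane_image, actin_image,
                                      pixel_size_um, depth_um = 1.5,
                                      n_rays = 90L, step_um = NULL) {
  step_um <- step_um %||% (pixel_size_um / 2)
  n <- length(contour$x)
  pick <- unique(round(seq(1, n, length.out = n_rays)))
  cx <- unname(contour$center["x"]); cy <- unname(contour$center["y"])
  s <- seq(-depth_um, depth_um, by = step_um)   # + inward
  memb_mat <- matrix(NA_real_, length(pick), length(s))
  act_mat <- matrix(NA_real_, length(pick), length(s))
  used <- 0L
  for (k in seq_along(pick)) {
    i <- pick[k]
    # inward unit vector (toward the centre along the radius)
    dx <- cx - contour$x[i]; dy <- cy - contour$y[i]
    dl <- sqrt(dx^2 + dy^2)
    if (dl == 0) next
    ux <- dx / dl; uy <- dy / dl
    rc <- .um_to_rc(contour$x[i] + s * ux, contour$y[i] + s * uy,
                    pixel_size_um)
    Im <- bilinear_sample(membrane_image, rc$row, rc$col)
    Ia <- bilinear_sample(actin_image, rc$row, rc$col)
    s_pk <- .refine_peak(s, Im)
    if (is.na(s_pk)) next
    # re-sample both channels so s = 0 sits at the membrane peak
    memb_mat[k, ] <- stats::approx(s - s_pk, Im, xout = s, rule = 2)$y
    act_mat[k, ] <- stats::approx(s - s_pk, Ia, xout = s, rule = 2)$y
    used <- used + 1L
  }
  if (used < length(pick) / 2) {
    stop(sprintf(
      "membrane peak not found on %d of %d rays (> 50%%): check the contour or image",
      length(pick) - used, length(pick)
    ))
  }
  I_memb <- colMeans(memb_mat, na.rm = TRUE)
  I_act <- colMeans(act_mat, na.rm = TRUE)
  if (max(I_act) <= 0 || !any(is.finite(I_act))) {
    stop("actin channel empty along the profiles")
  }
  delta <- .refine_peak(s, I_act)
  if (is.na(delta)) stop("no actin cortex peak found in the averaged profile")
  tail_n <- max(3L, length(s) %/% 5)
  I_out <- stats::median(I_act[seq_len(tail_n)])            # s most negative: outside
  I_V <- stats::median(I_act[seq(length(s) - tail_n + 1, length(s))])  # deep inside
  I_S <- max(I_act)
  structure(
    list(s_um = s, I_memb = I_memb, I_act = I_act,
         delta_um = delta, I_S = I_S, I_V = I_V, I_out = I_out,
         n_rays_used = used),
    class = "radial_profile"
  )
}

#' PSF width from sub-resolution bead images
#'
#' Detects isolated bright spots, rejects overlapping (closer than the
#' separation filter) and saturated beads, fits each remaining spot with a
#' 2D Gaussian, and returns the mean standard deviation as the PSF sigma.
#'
#' @param bead_image numeric matrix.
#' @param pixel_size_um pixel size (µm).
#' @param min_separation_px minimum centre separation; closer pairs are both
#'   excluded.
#' @param patch_px half-size of the fitting patch.
#' @param saturation_level optional intensity at/above which a bead is
#'   flagged saturated and excluded.
#' @return list with `sigma_um` (mean), `per_spot_um`, `n_spots`,
#'   `n_excluded`.
#' @export
psf_sigma_from_beads <- function(bead_image, pixel_size_um,
                                 min_separation_px = 8L, patch_px = 7L,
                                 saturation_level = NULL) {
  img <- bead_image
  bg <- stats::median(img)
  thr <- bg + 6 * max(stats::mad(img), 1e-12)
  nr <- nrow(img); nc <- ncol(img)
  # local maxima above threshold
  cand <- which(img > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rr <- max(1, r - 2):min(nr, r + 2); cc <- max(1, c - 2):min(nc, c + 2)
    keep[k] <- img[r, c] == max(img[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) stop("no beads detected")
  # merge plateau duplicates
  ord <- order(-img[cand])
  cand <- cand[ord, , drop = FALSE]
  sel <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!sel[k]) next
    d <- sqrt((cand[, 1] - cand[k, 1])^2 + (cand[, 2] - cand[k, 2])^2)
    dup <- d < 3 & seq_len(nrow(cand)) > k
    sel[dup] <- FALSE
  }
  cand <- cand[sel, , drop = FALSE]
  # separation filter: drop every member of a too-close pair
  n_excl <- 0L
  if (nrow(cand) > 1) {
    D <- as.matrix(stats::dist(cand))
    diag(D) <- Inf
    too_close <- apply(D, 1, min) < min_separation_px
    n_excl <- n_excl + sum(too_close)
    cand <- cand[!too_close, , drop = FALSE]
  }
  sigmas <- c()
  for (k in seq_len(nrow(cand))) {
    r0 <- cand[k, 1]; c0 <- cand[k, 2]
    if (!is.null(saturation_level) && img[r0, c0] >= saturation_level) {
      n_excl <- n_excl + 1L
      next
    }
    rr <- (r0 - patch_px):(r0 + patch_px); cc <- (c0 - patch_px):(c0 + patch_px)
    if (min(rr) < 1 || max(rr) > nr || min(cc) < 1 || max(cc) > nc) next
    patch <- img[rr, cc]
    df <- data.frame(
      z = as.vector(patch),
      r = rep(rr, times = length(cc)),
      c = rep(cc, each = length(rr))
    )
    fit <- try(minpack.lm::nlsLM(
      z ~ b + A * exp(-((r - r0f)^2 + (c - c0f)^2) / (2 * sg^2)),
      data = df,
      start = list(b = bg, A = img[r0, c0] - bg, r0f = r0, c0f = c0, sg = 1.5),
      lower = c(-Inf, 0, r0 - 3, c0 - 3, 0.3),
      upper = c(Inf, Inf, r0 + 3, c0 + 3, patch_px),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sigmas <- c(sigmas, stats::coef(fit)[["sg"]] * pixel_size_um)
  }
  if (length(sigmas) < 3) {
    stop(sprintf("fewer than 3 usable beads (%d fitted)", length(sigmas)))
  }
  list(sigma_um = mean(sigmas), per_spot_um = sigmas,
       n_spots = length(sigmas), n_excluded = n_excl)
}

#' Cortex thickness from the membrane-actin peak distance
#'
#' The ideal estimate is \eqn{h = 2\Delta} with \eqn{\Delta} the distance
#' between the membrane-fluorescence peak and the actin-cortex peak; actin
#' fluorescence in the liposome volume shifts the blurred cortex peak toward
#' the centre by \eqn{\delta = (\sigma^2/h)\ln[(I_{out} - I_S)/(I_V -
#' I_S)]}, giving \eqn{h = 2(\Delta - \delta)}.  Because delta itself
#' depends on h, the coupled system is solved exactly: substituting gives
#' \eqn{h^2 - 2\Delta h + 2\sigma^2 \ln r = 0}, and the physical root
#' (the one with \eqn{h \to 2\Delta} as \eqn{\sigma \to 0}) is
#' \eqn{h = \Delta + \sqrt{\Delta^2 - 2\sigma^2 \ln r}}.
#'
#' @param delta_um peak-to-peak distance Delta (µm), > 0.
#' @param sigma_um PSF standard deviation (µm), > 0.
#' @param I_S,I_V,I_out cortex peak, interior plateau and exterior plateau
#'   intensities; `I_S` must exceed both plateaus.
#' @param n_profiles number of profiles behind the estimate (metadata).
#' @return object of class `thickness_estimate`: list with `h_um`,
#'   `delta_shift_um` (the implied delta), `delta_um`, `sigma_um`,
#'   `log_ratio`, `n_profiles`.
#' @export
thickness_from_profile <- function(delta_um, sigma_um, I_S, I_V, I_out,
                                   n_profiles = NA_integer_) {
  stopifnot(delta_um > 0, sigma_um > 0)
  if (I_S <= max(I_V, I_out)) {
    stop("intensity ordering violated: cortex peak I_S must exceed I_V and I_out")
  }
  r <- (I_out - I_S) / (I_V - I_S)
  if (r <= 0) stop("intensity ordering violated: (I_out - I_S)/(I_V - I_S) <= 0")
  lr <- log(r)
  disc <- delta_um^2 - 2 * sigma_um^2 * lr
  if (disc < 0) {
    stop("profile inconsistent with model: Delta too small for the given sigma and intensity ratio")
  }
  h <- delta_um + sqrt(disc)
  structure(
    list(h_um = h, delta_shift_um = delta_um - h / 2, delta_um = delta_um,
         sigma_um = sigma_um, log_ratio = lr, n_profiles = n_profiles),
    class = "thickness_estimate"
  )
}

#' One-call cortex thickness estimate from a two-channel frame
#'
#' Convenience wrapper: extracts averaged normal profiles with
#' [normal_intensity_profiles] and solves [thickness_from_profile].
#'
#' For a sub-resolution cortex the observed peak height underestimates the
#' true cortex plateau intensity `I_S` (the PSF spreads the thin shell), so
#' using the raw peak in the intensity ratio would bias the shift term.
#' The wrapper therefore inverts the step-profile convolution at the peak:
#' given a current thickness iterate h, the true plateau satisfies
#' `peak = I_V A + I_S (B - A) + I_out (1 - B)` with
#' `A = Phi((-h + Delta)/sigma)` and `B = Phi(Delta/sigma)`, and h and
#' `I_S` are iterated to joint convergence (a few iterations suffice).
#'
#' @inheritParams normal_intensity_profiles
#' @param sigma_um PSF standard deviation (µm), e.g. from
#'   [psf_sigma_from_beads].
#' @param max_iter maximum deblurring iterations.
#' @return a `thickness_estimate` (see [thickness_from_profile]) with the
#'   profile attached as attribute `"profile"` and the deblurred plateau as
#'   `I_S_deblurred`.
#' @export
estimate_cortex_thickness <- function(contour, membrane_image, actin_image,
                                      pixel_size_um, sigma_um,
                                      depth_um = 1.5, n_rays = 90L,
                                      max_iter = 25L) {
  prof <- normal_intensity_profiles(contour, membrane_image, actin_image,
                                    pixel_size_um, depth_um = depth_um,
                                    n_rays = n_rays)
  Delta <- prof$delta_um
  peak <- prof$I_S
  h <- 2 * Delta                       # sigma -> 0 starting point
  I_S_true <- peak
  for (it in seq_len(max_iter)) {
    A <- stats::pnorm((-h + Delta) / sigma_um)
    B <- stats::pnorm(Delta / sigma_um)
    if (B - A < 1e-6) break            # degenerate geometry: keep raw peak
    I_S_new <- (peak - prof$I_V * A - prof$I_out * (1 - B)) / (B - A)
    if (I_S_new <= max(prof$I_V, prof$I_out)) break
    lr <- log((prof$I_out - I_S_new) / (prof$I_V - I_S_new))
    disc <- Delta^2 - 2 * sigma_um^2 * lr
    if (disc < 0) break                # keep the last consistent iterate
    h_new <- Delta + sqrt(disc)
    done <- abs(h_new - h) < 1e-6 && abs(I_S_new - I_S_true) < 1e-6
    h <- h_new; I_S_true <- I_S_new
    if (done) break
  }
  est <- thickness_from_profile(Delta, sigma_um, I_S_true, prof$I_V,
                                prof$I_out, n_profiles = prof$n_rays_used)
  est$I_S_deblurred <- I_S_true
  attr(est, "profile") <- prof
  est
}
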