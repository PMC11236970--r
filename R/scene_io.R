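# TIFF stack + JSON sidecar I/O for synthetic scenes and real data.

#' Read a (multi-page) TIFF stack as a list of matrices
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
}

#' Write a list of matrices as a 16-bit multi-page TIFF
#'
#' Intensities are scaled by a common factor into \[0, 1\]; the factor is
#' returned so sidecar metadata can make the scaling reversible.
#'
#' @param frames list of numeric matrices (or a single matrix).
#' @param path output file.
#' @return invisibly, the scale factor applied (original = stored * scale).
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  mx <- max(vapply(frames, max, numeric(1)), 1e-12)
  scaled <- lapply(frames, function(f) pmin(pmax(f / mx, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(mx)
}

#' Write a synthetic scene to disk
#'
#' One multi-page TIFF per channel plus a JSON sidecar holding the scene
#' truth and calibration, forming a self-describing no-download fixture.
#'
#' @param scene list with `membrane`, `actin` (lists of matrices), `truth`
#'   (a [scene_truth]), `pixel_size_um`, `frame_interval_s`, and optionally
#'   `surface` (a single-frame actin surface texture).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc_m <- write_stack(scene$membrane, file.path(dir, "membrane.tif"))
  sc_a <- write_stack(scene$actin, file.path(dir, "actin.tif"))
  sc_s <- if (!is.null(scene$surface)) {
    write_stack(scene$surface, file.path(dir, "surface.tif"))
  } else NULL
  tr <- scene$truth
  truth_json <- list(
    radius_um = tr$radius_um,
    mode_q = as.integer(names(tr$mode_amplitudes)),
    mode_re = Re(tr$mode_amplitudes),
    mode_im = Im(tr$mode_amplitudes),
    cortex_thickness_um = tr$cortex_thickness_um,
    psf_sigma_um = tr$psf_sigma_um,
    polarity_true = tr$polarity_true,
    order_param_true = tr$order_param_true,
    flow_divergence_per_s = tr$flow_divergence_per_s,
    seed = tr$seed
  )
  meta <- list(
    pixel_size_um = scene$pixel_size_um,
    frame_interval_s = scene$frame_interval_s,
    n_frames = length(scene$membrane),
    intensity_scale = list(membrane = sc_m, actin = sc_a, surface = sc_s),
    truth = truth_json
  )
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read a synthetic scene written by [write_scene]
#'
#' @param dir scene directory.
#' @return list with the same structure as the `scene` argument of
#'   [write_scene]; intensity scaling is undone from the sidecar.
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  rescale <- function(frames, s) lapply(frames, function(f) f * s)
  membrane <- rescale(read_stack(file.path(dir, "membrane.tif")),
                      meta$intensity_scale$membrane)
  actin <- rescale(read_stack(file.path(dir, "actin.tif")),
                   meta$intensity_scale$actin)
  surface <- if (file.exists(file.path(dir, "surface.tif"))) {
    rescale(read_stack(file.path(dir, "surface.tif")),
            meta$intensity_scale$surface)[[1]]
  } else NULL
  tj <- meta$truth
  amps <- complex(real = tj$mode_re, imaginary = tj$mode_im)
  names(amps) <- tj$mode_q
  truth <- scene_truth(
    radius_um = tj$radius_um, mode_amplitudes = amps,
    cortex_thickness_um = tj$cortex_thickness_um,
    psf_sigma_um = tj$psf_sigma_um,
    polarity_true = tj$polarity_true %||% NA_real_,
    order_param_true = tj$order_param_true %||% NA_real_,
    flow_divergence_per_s = tj$flow_divergence_per_s %||% NA_real_,
    seed = tj$seed %||% NA_integer_
  )
  list(membrane = membrane, actin = actin, surface = surface, truth = truth,
       pixel_size_um = meta$pixel_size_um,
       frame_interval_s = meta$frame_interval_s)
}
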