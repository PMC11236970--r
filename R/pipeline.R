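# Configuration, cohort synthesis and the end-to-end timelapse analysis.

#' Analysis configuration
#'
#' Bundles calibration and module parameters for the end-to-end pipeline.
#' Defaults correspond to the standard acquisition: 0.0938 µm/px, 6 s frame
#' interval, and a size gate excluding liposomes with mean radius below
#' 17.5 µm (deformation analysis is restricted to large liposomes, where
#' the relative bending cost h^2/R^2 permits measurable deformation).
#'
#' @param pixel_size_um pixel size (µm/px), > 0.
#' @param frame_interval_s frame interval (s), > 0.
#' @param channels named integer vector mapping `membrane` and `actin` to
#'   channel indices; must be distinct.
#' @param activation_frame first post-activation frame (index).
#' @param size_gate_um liposomes with initial mean radius below this are
#'   excluded from cohort summaries.
#' @param psf_sigma_um PSF standard deviation (µm) for thickness analysis.
#' @param n_spectrum_frames frames averaged in the power spectrum
#'   (default 20).
#' @param band_px polarity sampling band half-width (px).
#' @param seed integer seed for any stochastic stage.
#' @return list of class `analysis_config` with a `hash` attribute.
#' @export
analysis_config <- function(pixel_size_um = 0.0938, frame_interval_s = 6,
                            channels = c(membrane = 1L, actin = 2L),
                            activation_frame = 1L, size_gate_um = 17.5,
                            psf_sigma_um = 0.119, n_spectrum_frames = 20L,
                            band_px = 3, seed = 1L) {
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  if (channels["membrane"] == channels["actin"]) {
    stop("membrane and actin must map to distinct channels")
  }
  cfg <- list(
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    channels = channels, activation_frame = activation_frame,
    size_gate_um = size_gate_um, psf_sigma_um = psf_sigma_um,
    n_spectrum_frames = n_spectrum_frames, band_px = band_px, seed = seed
  )
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(cfg, class = "analysis_config", hash = h)
}

# analytic ensemble truth for a Helfrich-sampled contour series: the fitted
# scaling exponent and the autocorrelation first zero of the expected
# spectrum 1/(kappa q^4 + gamma q^2), q = 2..n_modes
spectrum_regime_truth <- function(kappa, gamma, n_modes = 24L) {
  q <- 2:n_modes
  p <- 1 / (kappa * q^4 + gamma * q^2)
  alpha <- -unname(stats::coef(stats::lm(log(p) ~ log(q)))[2])
  dth <- seq(0, pi, length.out = 20000)
  acfv <- vapply(dth, function(d) sum(p / 2 * cos(q * d)), numeric(1))
  iz <- which(acfv[-1] * acfv[-length(acfv)] <= 0 &
                acfv[-length(acfv)] > 0)[1]
  frac <- acfv[iz] / (acfv[iz] - acfv[iz + 1])
  theta_c <- (dth[iz] + frac * (dth[2] - dth[1])) * 180 / pi
  list(alpha = alpha, theta_c_deg = theta_c)
}

#' Cohort condition presets
#'
#' Parameter sets emulating the three cortex-architecture regimes:
#' `"arp23"` (branched, membrane-linked: disordered texture, low polarity,
#' negligible strain, bending-dominated q^-4 spectrum), `"mdia1"` (linear,
#' unlinked: ordered texture, moderate polarity from aster formation, small
#' strain, tension-dominated q^-2 spectrum with small deformation size) and
#' `"mixed"` (composite: ordered texture, high polarity, large strain,
#' bending-dominated spectrum with intermediate deformation size).
#'
#' @return named list of preset parameter lists.
#' @export
cohort_presets <- function() {
  list(
    arp23 = list(kappa = 1, gamma = 0, eps_max = 0.006, polarity = 0.10,
                 order = 0.29, h_um = 0.29),
    mdia1 = list(kappa = 0, gamma = 1, eps_max = 0.009, polarity = 0.20,
                 order = 0.39, h_um = 0.29),
    mixed = list(kappa = 1, gamma = 25, eps_max = 0.018, polarity = 0.30,
                 order = 0.43, h_um = 0.29)
  )
}

# scale a series of per-frame radius deviations (with a contraction ramp
# applied) so the maximum membrane strain over frames equals the target
.solve_eps_scale <- function(radius_um, dev_list, ramp, theta, eps_target) {
  eps_of_frame <- function(r) {
    if (min(r) <= 0) return(1)
    ct <- membrane_contour(r * cos(theta), r * sin(theta))
    1 - 4 * pi * ct$area_um2 / ct$perimeter_um^2
  }
  f <- function(s) {
    max(vapply(seq_along(dev_list), function(i) {
      eps_of_frame(radius_um + s * ramp[i] * dev_list[[i]])
    }, numeric(1))) - eps_target
  }
  stats::uniroot(f, lower = 1e-4, upper = 8, tol = 1e-9)$root
}

#' Synthesize a cohort of ground-truth liposome scenes
#'
#' Generates `n` two-channel timelapse scenes per the requested condition
#' preset: Helfrich-sampled contours with a fixed mode shape growing under a
#' linear contraction ramp calibrated so the final-frame membrane strain
#' equals the preset target, a polarized cortical actin intensity at the
#' preset polarity, a rendered bottom-surface filament texture at the preset
#' nematic order, and a cortex of the preset thickness.  The truth table
#' records every generating value, joinable to the pipeline output by `id`.
#'
#' @param preset preset name (see [cohort_presets]) or a preset list.
#' @param n number of liposomes.
#' @param seed integer seed.
#' @param n_frames frames per scene.
#' @param radius_range_um sampling range of liposome radii (default
#'   18-26 µm, the analysed size class).
#' @param pixel_size_um render pixel size.
#' @param frame_interval_s frame interval.
#' @param noise render with camera noise.
#' @param render if `FALSE`, skip image rendering and return contours +
#'   truth only (fast path for contour-level studies).
#' @param condition_label label stored in the truth table.
#' @return list with `scenes` (each: `membrane`, `actin`, `surface`,
#'   `contours`, `truth`, `pixel_size_um`, `frame_interval_s`) and `truth`
#'   (data.frame, one row per liposome).
#' @export
synthesize_cohort <- function(preset, n = 10L, seed = 1L, n_frames = 8L,
                              radius_range_um = c(18, 26),
                              pixel_size_um = 0.0938, frame_interval_s = 6,
                              noise = TRUE, render = TRUE,
                              condition_label = NULL) {
  if (is.character(preset)) {
    presets <- cohort_presets()
    if (!preset %in% names(presets)) {
      stop(sprintf("unknown preset '%s' (available: %s)", preset,
                   paste(names(presets), collapse = ", ")))
    }
    condition_label <- condition_label %||% preset
    preset <- presets[[preset]]
  }
  condition_label <- condition_label %||% "custom"
  stopifnot(n >= 1)
  regime <- spectrum_regime_truth(preset$kappa, preset$gamma)
  theta <- seq(-pi, pi, length.out = 361)[-1]
  scenes <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- (seed + 7919L * i) %% .Machine$integer.max
    sc <- with_seed(si, {
      R <- stats::runif(1, radius_range_um[1], radius_range_um[2])
      h <- min(max(stats::rnorm(1, preset$h_um, 0.03), 0.15), 0.6)
      # independent per-frame shapes under a linear contraction ramp,
      # scaled so the realized maximum membrane strain hits the preset
      base <- sample_contour_series(
        R, kappa = preset$kappa, gamma = preset$gamma, n_modes = 24,
        n_frames = n_frames, u_rms_um = 1, seed = si + 1L
      )
      dev_list <- lapply(base$amplitudes, function(a) {
        .modes_to_radius(0, a, theta)
      })
      ramp0 <- seq(1 / n_frames, 1, length.out = n_frames)
      s_fin <- .solve_eps_scale(R, dev_list, ramp0, theta, preset$eps_max)
      ramp <- ramp0 * s_fin
      ser <- sample_contour_series(
        R, kappa = preset$kappa, gamma = preset$gamma, n_modes = 24,
        n_frames = n_frames, u_rms_um = 1, amplitude_scale = ramp,
        fixed_shape = FALSE, seed = si + 1L
      )
      pol <- make_polarized_cortex(ser$contours[[n_frames]],
                                   preset$polarity, profile = "cosine")
      tex <- make_filament_texture(preset$order, n_filaments = 400,
                                   image_shape = c(256L, 256L),
                                   seed = si + 2L)
      membrane <- actin <- NULL
      if (render) {
        membrane <- vector("list", n_frames)
        actin <- vector("list", n_frames)
        # fixed image shape fitting every frame's contour plus margin
        marg <- 3 * 0.119 + 2
        ymax <- max(vapply(ser$contours, function(ct) max(ct$y), numeric(1)))
        xmax <- max(vapply(ser$contours, function(ct) max(ct$x), numeric(1)))
        shape <- c(ceiling((ymax + marg) / pixel_size_um) + 1L,
                   ceiling((xmax + marg) / pixel_size_um) + 1L)
        for (f in seq_len(n_frames)) {
          polf <- make_polarized_cortex(ser$contours[[f]], preset$polarity,
                                        profile = "cosine")
          fr <- render_two_channel_frame(
            ser$contours[[f]], cortex_thickness_um = h,
            psf_sigma_um = 0.119, cortex_weights = polf$intensity,
            # well-formed cortex regime: high surface-to-volume ratio
            intensities = list(I_S = 7.7, I_V = 1, I_out = 0.1, I_memb = 4),
            noise = noise, pixel_size_um = pixel_size_um,
            image_shape = shape, seed = si + 10L + f
          )
          membrane[[f]] <- fr$membrane
          actin[[f]] <- fr$actin
        }
      }
      eps_true <- max(vapply(ser$contours, function(ct) {
        1 - 4 * pi * ct$area_um2 / ct$perimeter_um^2
      }, numeric(1)))
      truth <- scene_truth(
        R, mode_amplitudes = ser$amplitudes[[n_frames]],
        cortex_thickness_um = h, psf_sigma_um = 0.119,
        polarity_true = pol$polarity_realized,
        order_param_true = tex$order_realized, seed = si
      )
      list(
        scene = list(membrane = membrane, actin = actin,
                     surface = tex$image, contours = ser$contours,
                     truth = truth, pixel_size_um = pixel_size_um,
                     frame_interval_s = frame_interval_s),
        row = data.frame(
          id = sprintf("%s_%02d", condition_label, i),
          condition = condition_label, radius_um = R,
          eps_memb_max_true = eps_true,
          polarity_true = pol$polarity_realized,
          order_true = tex$order_realized,
          alpha_true = regime$alpha,
          theta_c_true_deg = regime$theta_c_deg,
          h_true_um = h,
          stringsAsFactors = FALSE
        )
      )
    })
    scenes[[i]] <- sc$scene
    scenes[[i]]$id <- sprintf("%s_%02d", condition_label, i)
    rows[[i]] <- sc$row
  }
  list(scenes = scenes, truth = do.call(rbind, rows))
}

# analyse one scene; returns a one-row data.frame or signals an error
.analyse_scene <- function(scene, config) {
  px <- scene$pixel_size_um %||% config$pixel_size_um
  dt <- scene$frame_interval_s %||% config$frame_interval_s
  n_frames <- length(scene$membrane)
  contours <- lapply(seq_len(n_frames), function(f) {
    extract_contour(scene$membrane[[f]], px, smooth_modes = 60)
  })
  ts <- metric_timeseries(contours, scene$actin, px, dt,
                          band_px = config$band_px)
  R0 <- ts$R_mean_um[1]
  u_mat <- do.call(rbind, lapply(contours, function(ct) {
    radial_decomposition(ct)$u_um
  }))
  frames <- seq(config$activation_frame,
                min(n_frames, config$activation_frame +
                      config$n_spectrum_frames - 1))
  spec <- deformation_power_spectrum(u_mat, frames = frames)
  # fit over the physically populated mode band (q = 2..24; higher modes of
  # extracted contours sit on the vertex-noise floor)
  alpha <- fit_scaling_exponent(spec, q_range = c(2, 24))
  dsz <- angular_autocorrelation_size(u_mat[frames, , drop = FALSE])
  thick <- tryCatch(
    estimate_cortex_thickness(contours[[n_frames]],
                              scene$membrane[[n_frames]],
                              scene$actin[[n_frames]], px,
                              sigma_um = config$psf_sigma_um)$h_um,
    error = function(e) NA_real_
  )
  mean_S <- if (!is.null(scene$surface)) {
    of <- orientation_field(scene$surface, tensor_sigma_px = 2)
    nematic_order(of, spacing_px = 4)$mean_S
  } else NA_real_
  data.frame(
    id = scene$id %||% NA_character_,
    R_mean_um = R0,
    eps_memb_max = attr(ts, "eps_memb_max"),
    P_act_max = attr(ts, "P_act_max"),
    mean_S = mean_S,
    alpha = alpha,
    theta_c_deg = dsz$theta_c_deg,
    h_um = thick,
    n_frames = n_frames,
    stringsAsFactors = FALSE
  )
}

#' End-to-end timelapse analysis of a liposome cohort
#'
#' Runs contour extraction, shape metrics, polarity, deformation spectrum,
#' autocorrelation deformation size, surface nematic order and cortex
#' thickness on every scene; applies the size gate; aggregates per-condition
#' summaries.  A failing stage excludes that liposome with a recorded
#' reason, and the pipeline continues.
#'
#' @param config an [analysis_config].
#' @param scenes list of scenes (`synthesize_cohort()$scenes`, objects from
#'   [read_scene], or lists with `membrane`/`actin` frame lists); each may
#'   carry a `condition` field, else conditions are taken from `conditions`.
#' @param conditions optional character vector of per-scene condition
#'   labels.
#' @param out_dir optional directory for `per_liposome.csv` and
#'   `summary.csv` outputs.
#' @return list of class `cohort_summary`: `per_liposome` (data.frame),
#'   `per_condition` (mean, SD, median, IQR of each metric), `excluded`
#'   (data.frame id/reason), `config_hash`.
#' @export
run_timelapse_analysis <- function(config, scenes, conditions = NULL,
                                   out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(conditions)) {
    conditions <- vapply(scenes, function(s) s$condition %||%
                           sub("_[0-9]+$", "", s$id %||% "all"),
                         character(1))
  }
  rows <- list(); excl <- list()
  for (i in seq_along(scenes)) {
    id <- scenes[[i]]$id %||% sprintf("scene_%02d", i)
    res <- tryCatch(.analyse_scene(scenes[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1]] <- data.frame(
        id = id, reason = paste0("stage_failure: ", conditionMessage(res)),
        stringsAsFactors = FALSE
      )
      next
    }
    res$id <- id
    res$condition <- conditions[i]
    if (res$R_mean_um < config$size_gate_um) {
      excl[[length(excl) + 1]] <- data.frame(
        id = id, reason = "size_gate", stringsAsFactors = FALSE
      )
      next
    }
    rows[[length(rows) + 1]] <- res
  }
  per_liposome <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), reason = character(0))
  metrics <- c("eps_memb_max", "P_act_max", "mean_S", "alpha",
               "theta_c_deg", "h_um")
  per_condition <- NULL
  if (nrow(per_liposome)) {
    agg <- lapply(split(per_liposome, per_liposome$condition), function(d) {
      out <- data.frame(condition = d$condition[1], n = nrow(d))
      for (m in metrics) {
        v <- d[[m]]
        out[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
        out[[paste0(m, "_sd")]] <- stats::sd(v, na.rm = TRUE)
        out[[paste0(m, "_median")]] <- stats::median(v, na.rm = TRUE)
        out[[paste0(m, "_iqr")]] <- stats::IQR(v, na.rm = TRUE)
      }
      out
    })
    per_condition <- do.call(rbind, agg)
    rownames(per_condition) <- NULL
  }
  out <- structure(
    list(per_liposome = per_liposome, per_condition = per_condition,
         excluded = excluded, config_hash = attr(config, "hash")),
    class = "cohort_summary"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_liposome, file.path(out_dir, "per_liposome.csv"),
                     row.names = FALSE)
    if (!is.null(per_condition)) {
      utils::write.csv(per_condition, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(excluded, file.path(out_dir, "excluded.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d liposomes analysed, %d excluded\n",
              nrow(x$per_liposome), nrow(x$excluded)))
  if (!is.null(x$per_condition)) {
    print(x$per_condition[, c("condition", "n", "eps_memb_max_mean",
                              "P_act_max_mean", "alpha_mean",
                              "theta_c_deg_mean")])
  }
  invisible(x)
}
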