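#' @title Synthetic frame-stack simulator
#' @description
#' The simulator renders the statistical structure the analysis chain assumes
#' rather than detector physics: a bright skin region with a linear dose
#' response, a Gaussian optical blur, an optional slanted opaque edge, and
#' frame noise composed of Poisson shot noise and Gaussian read noise. The
#' PSF is applied to the noiseless scene, then per-frame noise is drawn.
#' @name simulate
NULL

# Separable Gaussian blur (sigma in px) with kernel normalized to unit sum.
# Falls back to identity for sigma = 0.
.gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  EBImage::imageData(EBImage::gblur(x, sigma = sigma_px,
                                    radius = 2 * ceiling(3 * sigma_px) + 1))
}

# Fractional pixel coverage of the bright side of a slanted edge:
# signed distance of each pixel centre to the edge line, clipped linear ramp
# one pixel wide in the normal direction (square-aperture approximation).
.edge_coverage <- function(shape_px, angle_deg, center) {
  nr <- shape_px[1]; nc <- shape_px[2]
  theta <- angle_deg * pi / 180
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  # edge line through `center` at `angle_deg` from the column (vertical) axis
  d <- ((cc - center[1]) - tan(theta) * (rr - center[2])) * cos(theta)
  pmin(pmax(0.5 + d, 0), 1)
}

# Noiseless expected frame (after PSF, before noise); also returns the
# pre-blur peak used for the saturation check.
.expected_frame <- function(scene, config, air_kerma) {
  skin <- rasterize_skin(scene)
  sig <- scene$response_slope * air_kerma * skin
  if (!is.na(scene$edge_angle_deg)) {
    cov <- .edge_coverage(scene$shape_px, scene$edge_angle_deg,
                          scene$edge_center)
    trans <- scene$edge_transmission + (1 - scene$edge_transmission) * cov
    sig <- sig * trans
  }
  peak <- scene$response_offset + max(sig)
  sigma_px <- scene$psf_sigma_mm / config$pixel_pitch_mm
  sig <- .gaussian_blur(sig, sigma_px)
  list(expected = scene$response_offset + pmax(sig, 0), peak = peak,
       skin = skin)
}

#' Simulate one frame stack
#'
#' Renders `config$n_frames` frames of a [synthetic_scene()] at a given air
#' kerma. The expected in-skin pixel value is
#' `response_offset + response_slope * air_kerma`; the Gaussian PSF is applied
#' to the noiseless scene, after which each frame draws Poisson shot noise
#' (`poisson_scale` photons per pixel unit; `Inf` disables it) and additive
#' Gaussian read noise. Pixels outside the skin polygon carry dark level plus
#' read noise only. Frames are clipped to `[0, full_scale]`.
#'
#' @param scene A [synthetic_scene()].
#' @param config A [detector_config()].
#' @param air_kerma Air kerma of the acquisition (mGy), >= 0.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param label Stack label recorded in the result.
#' @return A [frame_stack()].
#' @examples
#' sc <- synthetic_scene(c(64, 64), rect_polygon(64, 64, 8),
#'                       read_noise_sd = 0, poisson_scale = Inf)
#' st <- make_frame_stack(sc, detector_config(n_frames = 2), 0.5, seed = 1)
#' @export
make_frame_stack <- function(scene, config, air_kerma, seed,
                             label = c("raw", "flat", "dark")) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(config, "detector_config"))
  label <- match.arg(label)
  if (air_kerma < 0) stop("`air_kerma` must be >= 0", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)

  ef <- .expected_frame(scene, config, air_kerma)
  if (ef$peak > config$full_scale)
    stop(sprintf(paste0("saturation: expected peak %.1f exceeds full scale ",
                        "%g; reduce dose or response"),
                 ef$peak, config$full_scale),
         call. = FALSE)

  set.seed(as.integer(seed))
  n_px <- length(ef$expected)
  k <- config$n_frames
  sig <- ef$expected - scene$response_offset
  idx <- which(sig > 0)

  frames <- vector("list", k)
  shot_all <- if (is.finite(scene$poisson_scale) && length(idx)) {
    lam <- rep(sig[idx] * scene$poisson_scale, k)
    matrix(stats::rpois(length(lam), lam) / scene$poisson_scale,
           ncol = k)
  } else NULL
  for (i in seq_len(k)) {
    f <- matrix(scene$response_offset, scene$shape_px[1], scene$shape_px[2])
    if (is.null(shot_all)) f <- f + sig
    else f[idx] <- f[idx] + shot_all[, i]
    if (scene$read_noise_sd > 0)
      f <- f + matrix(stats::rnorm(n_px, sd = scene$read_noise_sd),
                      scene$shape_px[1], scene$shape_px[2])
    frames[[i]] <- pmin(pmax(f, 0), config$full_scale)
  }
  frame_stack(frames, config, label = label, air_kerma = air_kerma,
              meta = list(seed = as.integer(seed),
                          psf_sigma_mm = scene$psf_sigma_mm,
                          edge_angle_deg = scene$edge_angle_deg))
}

#' Simulate a signal-transfer-property exposure series
#'
#' Dose is varied through exposure time at a fixed dose rate, mirroring the
#' rig's practice: each element's air kerma is `dose_rate * exposure_s`. The
#' series includes a flat acquisition at the highest exposure (used for skin
#' contour detection at the highest experimental dose) and a dark stack.
#'
#' @param scene A [synthetic_scene()] without an edge overlay.
#' @param config A [detector_config()]; its `exposure_ms` is overridden per
#'   element.
#' @param exposure_times_ms Strictly increasing positive exposure times (ms).
#' @param dose_rate Dose rate (mGy/s).
#' @param seed Integer seed.
#' @return A list with elements `points` (a list of `list(air_kerma, stack)`),
#'   `flat`, `dark`, `dose_rate` and `exposure_times_ms`.
#' @export
make_stp_series <- function(scene, config, exposure_times_ms, dose_rate,
                            seed) {
  if (!length(exposure_times_ms))
    stop("`exposure_times_ms` must be non-empty", call. = FALSE)
  if (any(exposure_times_ms <= 0) || any(diff(exposure_times_ms) <= 0))
    stop("`exposure_times_ms` must be strictly increasing and positive",
         call. = FALSE)
  stopifnot(dose_rate >= 0)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L,
                      length(exposure_times_ms) + 2L)
  points <- vector("list", length(exposure_times_ms))
  for (i in seq_along(exposure_times_ms)) {
    t_ms <- exposure_times_ms[i]
    ak <- dose_rate * t_ms / 1000
    cfg_i <- config; cfg_i$exposure_ms <- t_ms
    points[[i]] <- list(air_kerma = ak,
                        stack = make_frame_stack(scene, cfg_i, ak,
                                                 seed = seeds[i]))
  }
  t_max <- max(exposure_times_ms)
  cfg_f <- config; cfg_f$exposure_ms <- t_max
  flat <- make_frame_stack(scene, cfg_f, dose_rate * t_max / 1000,
                           seed = seeds[length(seeds) - 1L], label = "flat")
  dark <- make_frame_stack(scene, config, 0, seed = seeds[length(seeds)],
                           label = "dark")
  list(points = points, flat = flat, dark = dark, dose_rate = dose_rate,
       exposure_times_ms = exposure_times_ms)
}

#' Build a slanted-edge test scene
#'
#' Places a straight opaque edge across the skin region at the requested
#' slant relative to the pixel matrix, mirroring the lead bar phantom used
#' for e-SFR measurement. The scene's analytic frequency response is
#' available through [gaussian_mtf_reference()] for its PSF.
#'
#' @param angle_deg Edge slant in degrees, `0 < angle_deg < 45`. Note the
#'   standard measurement window is 2-7 degrees; scenes outside it are
#'   constructed but flagged by [validate_edge_roi()] downstream.
#' @param psf_sigma_mm Gaussian PSF standard deviation (mm).
#' @param edge_transmission Fractional signal behind the edge.
#' @param config A [detector_config()].
#' @param shape_px Frame dimensions, default `c(256, 256)`.
#' @param margin Skin margin from the frame border (px).
#' @param ... Further arguments passed to [synthetic_scene()] (noise levels,
#'   response).
#' @return A [synthetic_scene()] with the edge overlay set.
#' @export
make_slanted_edge_scene <- function(angle_deg, psf_sigma_mm,
                                    edge_transmission = 0.05, config,
                                    shape_px = c(256, 256), margin = 16, ...) {
  if (!(angle_deg > 0 && angle_deg < 45))
    stop("`angle_deg` must lie in (0, 45)", call. = FALSE)
  synthetic_scene(shape_px = shape_px,
                  skin_polygon = rect_polygon(shape_px[1], shape_px[2],
                                              margin = margin),
                  psf_sigma_mm = psf_sigma_mm,
                  edge_angle_deg = angle_deg,
                  edge_transmission = edge_transmission, ...)
}

#' Lateral-contraction (thinning) models for a stretched skin
#'
#' Given the axial stretch factor `lambda = 1 + elongation/100`, a thinning
#' model returns the lateral width factor of the skin. Under volume
#' conservation the thickness factor then follows as
#' `1 / (lambda * width_factor)`.
#'
#' * `"uniaxial"` — incompressible uniaxial tension with isotropic lateral
#'   contraction: width and thickness both scale as `1/sqrt(lambda)`.
#' * `"pure_shear"` — width held fixed (clamped edges): width factor 1,
#'   thickness factor `1/lambda`.
#'
#' @param model Model name or a function `lambda -> width factor`.
#' @return A function of `lambda`.
#' @export
thinning_model <- function(model = c("uniaxial", "pure_shear")) {
  if (is.function(model)) return(model)
  model <- match.arg(model)
  switch(model,
         uniaxial   = function(lambda) 1 / sqrt(lambda),
         pure_shear = function(lambda) rep(1, length(lambda)))
}

#' Simulate a stretch series
#'
#' Scales the skin polygon along the stretch (column) axis by
#' `1 + elongation/100` with lateral contraction per `thinning_model`, keeping
#' track of the volume-conserved thickness `t0 * A0 / A`. The in-skin response
#' follows a linear mean-signal decline with elongation by default (the
#' behaviour observed at 70 kVp), with a thickness-coupled alternative where
#' the response scales with the thickness ratio.
#'
#' @param base_scene A [synthetic_scene()] for the unstretched skin.
#' @param elongations_pct Non-negative, sorted elongations in percent.
#' @param thinning Thinning model (see [thinning_model()]).
#' @param config A [detector_config()].
#' @param seed Integer seed.
#' @param t0_mm Initial skin thickness (mm), default 0.5.
#' @param air_kerma Air kerma per acquisition (mGy).
#' @param signal_model `"linear"` (default): relative in-skin signal
#'   `1 - decline_at_100 * elongation/100`; `"thickness"`: signal scales with
#'   the thickness ratio.
#' @param decline_at_100 Fractional signal decline at 100% elongation for the
#'   linear model (default 0.25).
#' @param rupture_limit_pct Elongations above this limit raise an error
#'   (default 120, the observed rupture point).
#' @return A list of per-step entries `list(elongation_pct, stack, scene,
#'   thickness_mm, area_ratio, signal_factor)`, plus attribute `t0_mm`.
#' @export
make_stretch_series <- function(base_scene, elongations_pct,
                                thinning = "uniaxial", config, seed,
                                t0_mm = 0.5, air_kerma = 0.5,
                                signal_model = c("linear", "thickness"),
                                decline_at_100 = 0.25,
                                rupture_limit_pct = 120) {
  stopifnot(inherits(base_scene, "synthetic_scene"), t0_mm > 0)
  signal_model <- match.arg(signal_model)
  if (any(elongations_pct < 0) || is.unsorted(elongations_pct))
    stop("`elongations_pct` must be non-negative and sorted", call. = FALSE)
  if (any(elongations_pct > rupture_limit_pct))
    stop(sprintf("elongation beyond rupture limit (%g%%)", rupture_limit_pct),
         call. = FALSE)
  wfun <- thinning_model(thinning)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(elongations_pct))

  center <- colMeans(base_scene$skin_polygon)
  out <- vector("list", length(elongations_pct))
  for (i in seq_along(elongations_pct)) {
    e <- elongations_pct[i]
    lambda <- 1 + e / 100
    w <- wfun(lambda)
    area_ratio <- lambda * w
    thickness <- t0_mm / area_ratio
    sf <- switch(signal_model,
                 linear = 1 - decline_at_100 * e / 100,
                 thickness = 1 / area_ratio)
    if (sf <= 0) stop("signal model drove the response non-positive",
                      call. = FALSE)
    poly <- cbind(center[1] + lambda * (base_scene$skin_polygon[, 1] - center[1]),
                  center[2] + w * (base_scene$skin_polygon[, 2] - center[2]))
    sc <- base_scene
    sc$skin_polygon <- poly
    sc$response_slope <- base_scene$response_slope * sf
    sc <- do.call(synthetic_scene, unclass(sc))  # re-validate geometry
    out[[i]] <- list(elongation_pct = e,
                     stack = make_frame_stack(sc, config, air_kerma,
                                              seed = seeds[i]),
                     scene = sc, thickness_mm = thickness,
                     area_ratio = area_ratio, signal_factor = sf)
  }
  attr(out, "t0_mm") <- t0_mm
  out
}

#' Analytic Gaussian MTF reference
#'
#' The modulation transfer function of a Gaussian PSF with standard deviation
#' `psf_sigma_mm`: `exp(-2 * pi^2 * sigma^2 * f^2)`. Serves as the closed-form
#' oracle for the slanted-edge chain; it equals 1 at zero frequency and its
#' half-height frequency is `sqrt(log(2) / (2 * pi^2 * sigma^2))`.
#'
#' @param psf_sigma_mm Gaussian PSF standard deviation (mm), >= 0.
#' @param frequencies_lp_per_mm Non-negative spatial frequencies (lp/mm).
#' @return Numeric vector of MTF values in `(0, 1]`.
#' @examples
#' gaussian_mtf_reference(0.2, c(0, 0.937))  # ~ c(1, 0.5)
#' @export
gaussian_mtf_reference <- function(psf_sigma_mm, frequencies_lp_per_mm) {
  stopifnot(psf_sigma_mm >= 0, all(frequencies_lp_per_mm >= 0))
  exp(-2 * pi^2 * psf_sigma_mm^2 * frequencies_lp_per_mm^2)
}
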