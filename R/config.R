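#' Detector and acquisition configuration
#'
#' Bundles the camera-side parameters of the imaging-skin rig: the effective
#' pixel pitch at the skin plane, the number of frames averaged per
#' acquisition, the exposure time, and the digitizer range. The defaults match
#' the reference setup: 51 um effective pitch, 10-frame averaging, 100 ms
#' exposure, and a 12-bit signal range (`full_scale = 4095`) stored in 16-bit
#' containers.
#'
#' @param pixel_pitch_mm Effective image pixel pitch at the skin plane (mm).
#' @param n_frames Number of frames averaged per acquisition.
#' @param exposure_ms Exposure time per frame (ms).
#' @param bit_depth Container bit depth.
#' @param full_scale Maximum representable pixel value (defaults to 12-bit
#'   signal range in a 16-bit container).
#' @return An object of class `detector_config`.
#' @examples
#' cfg <- detector_config()
#' cfg$pixel_pitch_mm
#' @export
detector_config <- function(pixel_pitch_mm = 0.051, n_frames = 10L,
                            exposure_ms = 100, bit_depth = 16L,
                            full_scale = 4095) {
  stopifnot(is.numeric(pixel_pitch_mm), length(pixel_pitch_mm) == 1L,
            pixel_pitch_mm > 0)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("`n_frames` must be a positive integer", call. = FALSE)
  if (!is.numeric(exposure_ms) || exposure_ms <= 0)
    stop("`exposure_ms` must be positive", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!(full_scale > 0 && full_scale <= 2^bit_depth - 1))
    stop("`full_scale` must lie in (0, 2^bit_depth - 1]", call. = FALSE)
  structure(
    list(pixel_pitch_mm = pixel_pitch_mm, n_frames = n_frames,
         exposure_ms = exposure_ms, bit_depth = bit_depth,
         full_scale = full_scale),
    class = "detector_config"
  )
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  cat(sprintf("  pixel pitch : %.4g mm (Nyquist %.3g lp/mm)\n",
              x$pixel_pitch_mm, 1 / (2 * x$pixel_pitch_mm)))
  cat(sprintf("  frames/data : %d\n", x$n_frames))
  cat(sprintf("  exposure    : %g ms\n", x$exposure_ms))
  cat(sprintf("  full scale  : %g (%d-bit container)\n",
              x$full_scale, x$bit_depth))
  invisible(x)
}

#' Synthetic imaging-skin scene
#'
#' Describes one virtual scene in front of the camera: a bright polygonal
#' skin region on a dark background, a per-pixel linear dose response, an
#' optional slanted opaque edge overlay, a Gaussian optical point-spread
#' function, and the per-frame noise model (Poisson shot noise plus Gaussian
#' read noise).
#'
#' The scene is resolution-independent where possible: the PSF width is given
#' in millimetres and converted through the detector pitch at render time.
#'
#' @param shape_px Integer vector `c(n_rows, n_cols)` of the frame size.
#' @param skin_polygon Two-column matrix of polygon vertices `(col, row)` in
#'   pixel coordinates (pixel-centre convention), strictly inside the frame.
#' @param response_slope Mean in-skin pixel value per unit air kerma (DN/mGy).
#' @param response_offset Dark level (DN).
#' @param psf_sigma_mm Gaussian PSF standard deviation (mm); 0 disables blur.
#' @param edge_angle_deg Slant of an optional opaque edge overlay, in degrees
#'   from the column axis; `NA` for no edge.
#' @param edge_transmission Fractional signal behind the edge, in `[0, 1)`.
#' @param edge_center Point `(col, row)` the edge line passes through;
#'   defaults to the polygon centroid.
#' @param read_noise_sd Per-frame additive Gaussian noise standard deviation
#'   (DN).
#' @param poisson_scale Photons per pixel unit for shot noise; `Inf` disables
#'   shot noise.
#' @return An object of class `synthetic_scene`.
#' @examples
#' sc <- synthetic_scene(shape_px = c(96, 96),
#'                       skin_polygon = rect_polygon(96, 96, margin = 10))
#' @export
synthetic_scene <- function(shape_px, skin_polygon,
                            response_slope = 3500, response_offset = 100,
                            psf_sigma_mm = 0, edge_angle_deg = NA_real_,
                            edge_transmission = 0, edge_center = NULL,
                            read_noise_sd = 2, poisson_scale = 5) {
  shape_px <- as.integer(shape_px)
  stopifnot(length(shape_px) == 2L, all(shape_px >= 8L))
  skin_polygon <- as.matrix(skin_polygon)
  if (ncol(skin_polygon) != 2L || nrow(skin_polygon) < 3L)
    stop("`skin_polygon` must be a matrix of >= 3 (col, row) vertices",
         call. = FALSE)
  if (any(skin_polygon[, 1] <= 1 | skin_polygon[, 1] >= shape_px[2] |
          skin_polygon[, 2] <= 1 | skin_polygon[, 2] >= shape_px[1]))
    stop("`skin_polygon` must lie strictly inside the frame", call. = FALSE)
  stopifnot(response_slope > 0, psf_sigma_mm >= 0,
            edge_transmission >= 0, edge_transmission < 1,
            read_noise_sd >= 0, poisson_scale > 0)
  if (is.null(edge_center))
    edge_center <- colMeans(skin_polygon)
  structure(
    list(shape_px = shape_px, skin_polygon = skin_polygon,
         response_slope = response_slope, response_offset = response_offset,
         psf_sigma_mm = psf_sigma_mm, edge_angle_deg = edge_angle_deg,
         edge_transmission = edge_transmission,
         edge_center = as.numeric(edge_center),
         read_noise_sd = read_noise_sd, poisson_scale = poisson_scale),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>", x$shape_px[1], "x", x$shape_px[2], "px\n")
  cat(sprintf("  response: %.4g DN/mGy + %.4g DN dark level\n",
              x$response_slope, x$response_offset))
  cat(sprintf("  PSF sigma: %g mm; noise: read sd %g DN, %g photons/DN\n",
              x$psf_sigma_mm, x$read_noise_sd, x$poisson_scale))
  if (!is.na(x$edge_angle_deg))
    cat(sprintf("  edge overlay at %.3g deg, transmission %.3g\n",
                x$edge_angle_deg, x$edge_transmission))
  invisible(x)
}

#' Axis-aligned rectangular polygon helper
#'
#' Convenience constructor for a rectangular skin region centred in a frame,
#' `margin` pixels away from every border.
#'
#' @param n_rows,n_cols Frame size in pixels.
#' @param margin Distance from the frame border (px).
#' @return A 4 x 2 matrix of `(col, row)` vertices.
#' @export
rect_polygon <- function(n_rows, n_cols, margin = 10) {
  stopifnot(margin > 0, n_rows > 2 * margin, n_cols > 2 * margin)
  cbind(c(1 + margin, n_cols - margin, n_cols - margin, 1 + margin),
        c(1 + margin, 1 + margin, n_rows - margin, n_rows - margin))
}

#' Rasterize a scene polygon onto the pixel grid
#'
#' Returns a logical matrix marking pixels whose centres fall inside the skin
#' polygon (boundary pixels count as inside).
#'
#' @param scene A [synthetic_scene()].
#' @return Logical matrix of dimension `scene$shape_px`.
#' @export
rasterize_skin <- function(scene) {
  nr <- scene$shape_px[1]; nc <- scene$shape_px[2]
  cc <- rep(seq_len(nc), each = nr)
  rr <- rep(seq_len(nr), times = nc)
  inside <- pracma::inpolygon(cc, rr,
                              scene$skin_polygon[, 1], scene$skin_polygon[, 2],
                              boundary = TRUE)
  matrix(inside, nrow = nr, ncol = nc)
}
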