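# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a check's stated conditions need the
# full-scale geometry.

tiny_config <- function(n_frames = 2L, ...) {
  detector_config(n_frames = n_frames, ...)
}

# Noiseless scene: deterministic expected values for exact assertions.
noiseless_scene <- function(shape = c(96, 96), margin = 10.5, ...) {
  synthetic_scene(shape_px = shape,
                  skin_polygon = rect_polygon(shape[1], shape[2], margin),
                  read_noise_sd = 0, poisson_scale = Inf, ...)
}

noisy_scene <- function(shape = c(96, 96), margin = 10.5, ...) {
  synthetic_scene(shape_px = shape,
                  skin_polygon = rect_polygon(shape[1], shape[2], margin),
                  ...)
}

# Study-condition STP series: 8 exposures 20-500 ms, 10-frame averaging,
# ROI >= 1e5 px on the 12-bit scale (full-scale geometry).
acc_stp_conditions <- function() {
  list(config = detector_config(),
       scene = synthetic_scene(c(340, 340), rect_polygon(340, 340, 6.5)),
       exposure_times_ms = c(20, 50, 100, 150, 200, 300, 400, 500),
       dose_rate = 2)
}

# Study-condition stretch series: 0-100% in 20% steps, volume-conserved
# thinning, linear 25% mean-signal decline at 100%, calibrated noise.
acc_stretch_series <- function(seed, shape = 340) {
  lambda_max <- 2
  margin <- ceiling(shape / 2 - (shape / 2 - 2) / lambda_max) + 0.5
  base <- synthetic_scene(c(shape, shape),
                          rect_polygon(shape, shape, margin))
  cfg <- detector_config()
  series <- make_stretch_series(base, seq(0, 100, by = 20), config = cfg,
                                seed = seed)
  dark <- make_frame_stack(base, cfg, 0, seed = seed + 1L, label = "dark")
  list(series = series, dark = dark, base = base, config = cfg)
}

# Dark-corrected mean frame of a simulated slanted-edge acquisition, plus
# the interior sub-image used as the edge ROI.
sim_edge_matrix <- function(angle_deg, psf_sigma_mm, seed = 42,
                            shape = c(340, 340), noiseless = FALSE,
                            air_kerma = 0.2) {
  cfg <- detector_config()
  extra <- if (noiseless) list(read_noise_sd = 0, poisson_scale = Inf)
           else list()
  sc <- do.call(make_slanted_edge_scene,
                c(list(angle_deg = angle_deg, psf_sigma_mm = psf_sigma_mm,
                       config = cfg, shape_px = shape, margin = 14),
                  extra))
  st <- make_frame_stack(sc, cfg, air_kerma, seed = seed)
  m <- average_frames(st) - sc$response_offset
  sub <- m[41:(shape[1] - 40), 31:(shape[2] - 30)]
  list(roi = edge_roi(sub, pitch_mm = cfg$pixel_pitch_mm), scene = sc,
       config = cfg)
}

# Scalar per-pixel loop oracle for the gain/offset correction, kept
# independent of the vectorized implementation.
flat_field_loop_oracle <- function(raw, dark, flat, mask) {
  gain_vals <- c()
  for (i in seq_len(nrow(raw)))
    for (j in seq_len(ncol(raw)))
      if (mask[i, j]) gain_vals <- c(gain_vals, flat[i, j] - dark[i, j])
  m <- sum(gain_vals) / length(gain_vals)
  out <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (i in seq_len(nrow(raw)))
    for (j in seq_len(ncol(raw)))
      if (mask[i, j])
        out[i, j] <- (raw[i, j] - dark[i, j]) /
          (flat[i, j] - dark[i, j]) * m
  out
}

# |sinc| envelope of a square pixel aperture of pitch p (lp/mm frequencies).
pixel_aperture_sinc <- function(f_lp_mm, pitch_mm) {
  x <- pi * f_lp_mm * pitch_mm
  ifelse(x == 0, 1, abs(sin(x) / x))
}
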