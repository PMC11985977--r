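test_that("noiseless frames carry exact expected values", {
  cfg <- tiny_config()
  sc <- noiseless_scene()
  skin <- rasterize_skin(sc)

  # zero dose: every pixel sits at the dark level
  st0 <- make_frame_stack(sc, cfg, 0, seed = 1)
  for (f in st0$frames) expect_true(all(f == sc$response_offset))

  # linear construction: in-skin mean equals offset + slope * air kerma
  ak <- 0.37
  st <- make_frame_stack(sc, cfg, ak, seed = 1)
  m <- average_frames(st)
  expect_equal(unique(as.numeric(m[skin])),
               sc$response_offset + sc$response_slope * ak)
  expect_equal(unique(as.numeric(m[!skin])), sc$response_offset)
})

test_that("identical seeds give bit-identical stacks", {
  cfg <- tiny_config()
  sc <- noisy_scene()
  a <- make_frame_stack(sc, cfg, 0.4, seed = 123)
  b <- make_frame_stack(sc, cfg, 0.4, seed = 123)
  expect_identical(a$frames, b$frames)
  c <- make_frame_stack(sc, cfg, 0.4, seed = 124)
  expect_false(identical(a$frames, c$frames))
})

test_that("expected values above full scale raise a saturation error", {
  cfg <- tiny_config()
  sc <- noiseless_scene(response_slope = 5000)
  expect_error(make_frame_stack(sc, cfg, 1.0, seed = 1), "saturation")
  # just below full scale is fine: 100 + 5000*0.79 = 4050 < 4095
  expect_s3_class(make_frame_stack(sc, cfg, 0.79, seed = 1), "frame_stack")
})

test_that("STP series computes air kerma as dose rate times exposure", {
  cfg <- tiny_config()
  sc <- noiseless_scene()
  ser <- make_stp_series(sc, cfg, c(100, 200), dose_rate = 2, seed = 5)
  expect_equal(ser$points[[1]]$air_kerma, 0.2)
  expect_equal(ser$points[[2]]$air_kerma, 0.4)
  expect_equal(ser$flat$label, "flat")
  expect_equal(ser$dark$label, "dark")
  expect_equal(ser$dark$air_kerma, 0)
  expect_error(make_stp_series(sc, cfg, numeric(0), 2, seed = 1),
               "non-empty")
  expect_error(make_stp_series(sc, cfg, c(100, 50), 2, seed = 1),
               "increasing")
})

test_that("noiseless STP series is exactly linear through the pipeline", {
  cfg <- tiny_config()
  sc <- noiseless_scene()
  ser <- make_stp_series(sc, cfg, c(50, 100, 200, 400), dose_rate = 2,
                         seed = 5)
  ana <- stp_analysis(ser)
  expect_equal(ana$fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(ana$fit$slope, sc$response_slope, tolerance = 1e-9)
  expect_equal(ana$fit$intercept, 0, tolerance = 1e-9)
  expect_true(ana$fit$is_linear)
  expect_equal(ana$fit$max_relative_deviation, 0, tolerance = 1e-9)
})

test_that("slanted-edge scenes respect the requested slant and PSF", {
  expect_error(make_slanted_edge_scene(0, 0.1, config = detector_config()),
               "angle")
  expect_error(make_slanted_edge_scene(45, 0.1, config = detector_config()),
               "angle")
  sc <- make_slanted_edge_scene(5, 0, config = detector_config(),
                                shape_px = c(96, 96), margin = 10.5,
                                read_noise_sd = 0, poisson_scale = Inf)
  expect_equal(sc$edge_angle_deg, 5)
  # degenerate PSF: the rendered edge is an ideal (aperture-limited) step
  st <- make_frame_stack(sc, tiny_config(), 0.3, seed = 1)
  m <- average_frames(st)
  inskin <- m[48, 20:75]
  expect_true(min(inskin) < 0.2 * max(inskin))  # dark side present
  expect_true(all(diff(inskin) >= -1e-9))        # monotone step
})

test_that("stretch series obeys volume conservation and the rupture limit", {
  cfg <- tiny_config()
  base <- noiseless_scene(shape = c(140, 140), margin = 45.5)

  # identity at zero elongation
  ser0 <- make_stretch_series(base, 0, config = cfg, seed = 3)
  expect_equal(ser0[[1]]$scene$skin_polygon, base$skin_polygon)
  expect_equal(ser0[[1]]$scene$response_slope, base$response_slope)
  expect_equal(ser0[[1]]$thickness_mm, 0.5)

  # the full protocol: 0-120% in 20% steps gives seven stacks
  ser <- make_stretch_series(base, seq(0, 120, by = 20), config = cfg,
                             seed = 3)
  expect_length(ser, 7L)

  expect_error(make_stretch_series(base, c(0, 130), config = cfg, seed = 3),
               "rupture")
  expect_error(make_stretch_series(base, c(40, 20), config = cfg, seed = 3),
               "sorted")
})

test_that("thinning models follow the closed form t = t0 * A0 / A", {
  t0 <- 0.5
  for (model in c("uniaxial", "pure_shear")) {
    wfun <- thinning_model(model)
    for (e in c(20, 60, 100, 120)) {
      lambda <- 1 + e / 100
      area_ratio <- lambda * wfun(lambda)
      # closed-form volume conservation, evaluated independently
      t_expected <- t0 * 1 / area_ratio
      base <- noiseless_scene(shape = c(200, 200), margin = 65.5)
      ser <- make_stretch_series(base, e, thinning = model,
                                 config = tiny_config(), seed = 1,
                                 t0_mm = t0)
      expect_equal(ser[[1]]$thickness_mm, t_expected, tolerance = 1e-12)
      # thickness x area ratio is constant (= t0) for every model
      expect_equal(ser[[1]]$thickness_mm * ser[[1]]$area_ratio, t0,
                   tolerance = 1e-12)
    }
  }
  # at 100% elongation the two models differ by a factor sqrt(2)
  lam <- 2
  t_uni <- 1 / (lam * thinning_model("uniaxial")(lam))
  t_ps <- 1 / (lam * thinning_model("pure_shear")(lam))
  expect_equal(t_uni / t_ps, sqrt(2), tolerance = 1e-12)
  expect_equal(t_ps, 0.5, tolerance = 1e-12)
})

test_that("the Gaussian MTF reference matches its closed-form inversion", {
  expect_equal(gaussian_mtf_reference(0, c(0, 1, 5)), rep(1, 3))
  expect_equal(gaussian_mtf_reference(0.3, 0), 1)
  # half-height frequency for sigma = 0.2 mm, confirmed by root finding
  sigma <- 0.2
  f50_closed <- sqrt(log(2) / (2 * pi^2 * sigma^2))
  f50_numeric <- uniroot(function(f) gaussian_mtf_reference(sigma, f) - 0.5,
                         c(0.01, 5), tol = 1e-10)$root
  expect_equal(f50_closed, f50_numeric, tolerance = 1e-8)
  expect_equal(f50_closed, 0.937, tolerance = 1e-3)
})
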