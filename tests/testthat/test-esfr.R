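# Simulated edge fixtures shared across the blocks below (built once).
edge5 <- sim_edge_matrix(5, 0.2, seed = 42)
edge10 <- sim_edge_matrix(10, 0.2, seed = 43)
step5 <- sim_edge_matrix(5, 0, seed = 44, noiseless = TRUE)

test_that("edge validation enforces the slant window and side balance", {
  v5 <- validate_edge_roi(edge5$roi)
  expect_true(v5$valid)
  expect_equal(v5$angle_deg, 5, tolerance = 0.04)  # within +/- 0.2 deg

  v10 <- validate_edge_roi(edge10$roi)
  expect_false(v10$valid)
  expect_match(paste(v10$reasons, collapse = " "), "angle outside")
  expect_equal(v10$angle_deg, 10, tolerance = 0.05)

  # ROI with ~80% bright pixels: edge placed far off-centre
  p <- edge5$roi$pixels
  sub <- p[, seq_len(round(ncol(p) * 0.62))]  # cut away most of the dark side
  vimb <- validate_edge_roi(edge_roi(sub, pitch_mm = 0.051))
  expect_false(vimb$valid)
  expect_match(paste(vimb$reasons, collapse = " "), "side imbalance")
})

test_that("edge-line estimation recovers constructed geometries", {
  # noiseless step shifting exactly 0.5 px per row (coverage-ramp edge)
  nr <- 60; nc <- 80
  pos <- 20 + 0.5 * (seq_len(nr) - 1)
  m <- matrix(0, nr, nc)
  for (r in seq_len(nr))
    m[r, ] <- pmin(pmax(0.5 + (seq_len(nc) - pos[r]), 0), 1) * 1000
  line <- estimate_edge_line(edge_roi(m, pitch_mm = 0.051))
  expect_equal(line$slope, 0.5, tolerance = 1e-6)
  expect_lt(line$residual_rms, 1e-6)

  # axis-aligned ideal step: constant positions, zero slope
  m0 <- matrix(0, 40, 64); m0[, 33:64] <- 900
  line0 <- estimate_edge_line(edge_roi(m0, pitch_mm = 0.051))
  expect_equal(line0$slope, 0, tolerance = 1e-9)
  expect_equal(unique(round(line0$positions, 6)), 32.5)

  # noisy simulated edge at 4 degrees: angle within +/- 0.3 deg
  e4 <- sim_edge_matrix(4, 0.2, seed = 45)
  l4 <- estimate_edge_line(e4$roi)
  expect_equal(l4$angle_deg, 4, tolerance = 0.075)

  expect_error(estimate_edge_line(edge_roi(matrix(1, 20, 20), 0.051)),
               "no detectable edge")
})

test_that("the oversampled ESF matches step and Gaussian-CDF oracles", {
  line <- estimate_edge_line(step5$roi)
  esf <- build_esf(step5$roi, line)
  # ideal step: transition centred at distance 0 within half a bin
  lo <- max(esf$esf[esf$distance_px < -1])
  hi <- min(esf$esf[esf$distance_px > 1])
  amp <- max(esf$esf) - min(esf$esf)
  # both plateaus flat: no residual transition outside +/- 1 px
  expect_lt((lo - min(esf$esf)) / amp, 0.02)
  expect_gt((hi - min(esf$esf)) / amp, 0.98)
  mid <- (max(esf$esf) + min(esf$esf)) / 2
  crossing <- esf$distance_px[which(esf$esf > mid)[1]]
  expect_lt(abs(crossing), 0.5 + 1 / esf$oversample)
  # monotone for a noiseless step
  expect_true(all(diff(esf$esf) >= -1e-9))

  # Gaussian-blurred edge: ESF equals the blurred-aperture CDF oracle
  eg <- sim_edge_matrix(5, 0.2, seed = 46, noiseless = TRUE)
  lg <- estimate_edge_line(eg$roi)
  eG <- build_esf(eg$roi, lg)
  sigma_px <- 0.2 / 0.051
  # independent oracle: step (x) 1-px box (x) Gaussian, by quadrature
  u <- seq(-0.5, 0.5, length.out = 201)
  ref <- vapply(eG$distance_px,
                function(d) mean(pnorm((d - u) / sigma_px)), numeric(1))
  amp <- max(eG$esf) - min(eG$esf)
  scaled <- (eG$esf - min(eG$esf)) / amp
  keep <- abs(eG$distance_px) < 5 * sigma_px
  expect_lt(max(abs(scaled - ref)[keep]), 0.01)

  # an exactly axis-aligned edge has no sub-pixel phase diversity
  m0 <- matrix(0, 80, 80); m0[, 41:80] <- 900
  line0 <- list(intercept = 40.5, slope = 0)
  expect_error(build_esf(edge_roi(m0, 0.051), line0),
               "insufficient slant coverage")
})

test_that("the SFR chain matches the analytic Gaussian MTF", {
  curve <- esfr_analysis(edge5$roi)
  ref <- gaussian_mtf_reference(0.2, curve$frequency_lp_mm)
  band <- curve$frequency_lp_mm <= 0.8 * curve$nyquist_lp_mm
  expect_lt(max(abs(curve$value - ref)[band]), 0.02)
  expect_equal(curve$value[1], 1, tolerance = 1e-6)
  expect_equal(curve$sfr50, sqrt(log(2) / (2 * pi^2 * 0.2^2)),
               tolerance = 0.03)
  expect_true(curve$sfr10 > curve$sfr50)
})

test_that("an unblurred step edge follows the pixel-aperture sinc envelope", {
  curve <- esfr_analysis(step5$roi)
  env <- pixel_aperture_sinc(curve$frequency_lp_mm, 0.051)
  expect_true(all(curve$value <= env + 0.025))
  expect_lt(max(abs(curve$value - env)), 0.025)
})

test_that("summary crossings interpolate and flag missing ones", {
  # constructed curve crossing 0.5 exactly at a grid frequency
  cv <- list(frequency_lp_mm = c(0, 1, 2, 3, 4),
             value = c(1, 0.8, 0.5, 0.2, 0.05))
  s <- sfr_summary(cv)
  expect_equal(s$sfr50, 2)
  expect_equal(s$sfr10, 3 + (0.1 - 0.2) / (0.05 - 0.2))  # linear interp
  expect_false(s$sfr50_beyond_nyquist)

  flat <- list(frequency_lp_mm = 0:5, value = rep(1, 6))
  sf <- sfr_summary(flat)
  expect_true(sf$sfr50_beyond_nyquist && sf$sfr10_beyond_nyquist)
  expect_true(is.na(sf$sfr50) && is.na(sf$sfr10))
})

test_that("frequencies scale inversely with pitch (pure unit transform)", {
  line <- estimate_edge_line(edge5$roi)
  esf <- build_esf(edge5$roi, line)
  c1 <- esf_to_sfr(esf, pitch_mm = 0.051)
  c2 <- esf_to_sfr(esf, pitch_mm = 0.051 / 2)
  expect_equal(c2$sfr50 / c1$sfr50, 2, tolerance = 1e-6)
  expect_equal(c2$nyquist_lp_mm, 2 * c1$nyquist_lp_mm)
})

test_that("transposing the ROI leaves the summary unchanged", {
  horiz <- edge_roi(t(edge5$roi$pixels), pitch_mm = 0.051,
                    orientation = "horizontal")
  cv <- esfr_analysis(edge5$roi)
  ch <- esfr_analysis(horiz)
  expect_equal(ch$sfr50, cv$sfr50, tolerance = 1e-9)
  expect_equal(ch$sfr10, cv$sfr10, tolerance = 1e-9)
})

test_that("more blur strictly degrades SFR50 and SFR10", {
  s50 <- c(); s10 <- c()
  for (sig in c(0.1, 0.2, 0.4)) {
    e <- sim_edge_matrix(4.5, sig, seed = 47)
    cv <- esfr_analysis(e$roi)
    s50 <- c(s50, cv$sfr50); s10 <- c(s10, cv$sfr10)
  }
  expect_true(all(diff(s50) < 0))
  expect_true(all(diff(s10) < 0))
})
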