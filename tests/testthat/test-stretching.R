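test_that("elongation follows (L - L0)/L0 * 100", {
  expect_equal(elongation(50, 60), 20)    # the 1 cm step on a 50 mm skin
  expect_equal(elongation(50, 50), 0)
  expect_equal(elongation(50, 110), 120)  # the rupture elongation
  expect_error(elongation(50, 45), "compression")
  expect_error(elongation(0, 10), "> 0")
})

test_that("volume-conserved thickness inverts the area ratio", {
  expect_equal(thickness_volume_conserved(0.5, 1), 0.5)
  expect_equal(thickness_volume_conserved(0.5, 2), 0.25)
  # the 0.5 -> 0.26 mm endpoint implies an area ratio of ~1.923;
  # the round trip restores it
  ratio <- 0.5 / 0.26
  expect_equal(thickness_volume_conserved(0.5, ratio), 0.26,
               tolerance = 1e-12)
  expect_equal(0.5 / thickness_volume_conserved(0.5, ratio), ratio,
               tolerance = 1e-12)
  expect_error(thickness_volume_conserved(0.5, 0.9), "shrink")
})

test_that("area ratios from rasterized masks track the scale factors", {
  mk <- function(h, w, H = 220, W = 220) {
    m <- matrix(FALSE, H, W)
    r0 <- round((H - h) / 2); c0 <- round((W - w) / 2)
    m[(r0 + 1):(r0 + round(h)), (c0 + 1):(c0 + round(w))] <- TRUE
    roi_mask(m)
  }
  r0 <- mk(150, 150)
  expect_equal(area_ratio_from_rois(r0, r0), 1)
  r12 <- mk(150, 150 * 1.2)
  expect_equal(area_ratio_from_rois(r0, r12), 1.2, tolerance = 0.01)
  r2 <- mk(150 * 0.913, 150 * 1.2)
  expect_equal(area_ratio_from_rois(r0, r2), 1.2 * 0.913,
               tolerance = 0.01)
})

test_that("mean-removed histograms ignore constant offsets", {
  set.seed(8)
  img <- matrix(rnorm(64 * 64, 900, 12), 64, 64)
  roi <- roi_mask(matrix(TRUE, 64, 64))
  rng <- c(-60, 60)
  p <- mean_removed_histogram(img, roi, 256, rng)
  q <- mean_removed_histogram(img + 100, roi, 256, rng)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, q)

  # constant image: all mass in one bin, centred on zero
  pc <- mean_removed_histogram(matrix(5, 8, 8), roi_mask(matrix(TRUE, 8, 8)))
  expect_equal(sum(pc > 0), 1L)
  expect_equal(sum(pc), 1)

  # Gaussian pixels reproduce the density within multinomial error
  mids <- attr(p, "mids")
  width <- diff(attr(p, "breaks"))[1]
  dens <- dnorm(mids, 0, 12) * width
  expect_lt(max(abs(p - dens / sum(dens))), 6 / sqrt(length(img)))
})

test_that("Bhattacharyya distance matches hand-evaluated cases", {
  expect_equal(as.numeric(bhattacharyya_distance(c(0.3, 0.7), c(0.3, 0.7))),
               0, tolerance = 1e-12)
  d <- bhattacharyya_distance(c(1, 0), c(0.5, 0.5))
  expect_equal(as.numeric(d), -log(sqrt(0.5)), tolerance = 1e-12)
  disj <- bhattacharyya_distance(c(1, 0), c(0, 1))
  expect_true(is.infinite(disj))
  expect_equal(attr(disj, "disjoint_mass"), 1)
  expect_error(bhattacharyya_distance(c(0.5, 0.6), c(0.5, 0.5)),
               "normalized")
  expect_error(bhattacharyya_distance(c(1, 0), c(0.5, 0.25, 0.25)),
               "equal bin")
})

test_that("Bhattacharyya distance is symmetric, non-negative, zero on id", {
  set.seed(17)
  for (i in 1:25) {
    p <- rgamma(64, 1); p <- p / sum(p)
    q <- rgamma(64, 1); q <- q / sum(q)
    dpq <- as.numeric(bhattacharyya_distance(p, q))
    dqp <- as.numeric(bhattacharyya_distance(q, p))
    expect_gte(dpq, 0)
    expect_equal(dpq, dqp, tolerance = 1e-12)
    expect_equal(as.numeric(bhattacharyya_distance(p, p)), 0,
                 tolerance = 1e-12)
  }
})

test_that("trend fits handle linear, noisy and degenerate metrics", {
  e <- seq(0, 100, by = 20)
  tf <- trend_vs_elongation(e, 1800 - 4.5 * e)
  expect_equal(tf$r_squared, 1)
  expect_lt(tf$slope, 0)

  set.seed(9)
  tf2 <- trend_vs_elongation(e, 1800 - 4.5 * e + rnorm(length(e), sd = 40))
  expect_gt(tf2$r_squared, 0.95)
  expect_lt(tf2$slope, 0)

  tf3 <- trend_vs_elongation(e, rep(700, length(e)))
  expect_equal(tf3$slope, 0, tolerance = 1e-12)
  expect_equal(tf3$r_squared, 0)
  expect_true(tf3$degenerate_response)
})

test_that("zone partitions are disjoint, exhaustive and border-ordered", {
  # rasterized disc
  H <- 121
  cc <- matrix(rep(1:H, each = H), H, H)
  rr <- matrix(rep(1:H, times = H), H, H)
  disc <- (rr - 61)^2 + (cc - 61)^2 <= 50^2
  roi <- roi_mask(disc)

  expect_identical(zone_partition(roi, 1)[[1]], disc)

  z2 <- zone_partition(roi, 2)
  expect_equal(sum(z2[[1]] & z2[[2]]), 0L)            # disjoint
  expect_identical(z2[[1]] | z2[[2]], disc)           # cover exactly
  # equal-area split by distance percentile, within 10%
  expect_lt(abs(sum(z2[[1]]) - sum(z2[[2]])) / sum(disc), 0.1)
  # distance-transform oracle: the 50% split radius of a disc is R/sqrt(2)
  inner <- (rr - 61)^2 + (cc - 61)^2 <= (50 / sqrt(2))^2
  expect_lt(sum(xor(z2[[2]], inner)) / sum(disc), 0.1)

  z5 <- zone_partition(roi, 5)
  expect_identical(Reduce(`|`, z5), disc)
  expect_equal(sum(vapply(z5, sum, numeric(1))), sum(disc))

  expect_error(zone_partition(roi_mask(matrix(c(TRUE, TRUE), 1, 2)), 3),
               "too small")
})

test_that("stretch analysis recovers generator thinning and MPV decline", {
  fx <- acc_stretch_series(seed = 314, shape = 300)
  ana <- stretch_analysis(fx$series, dark_stack = fx$dark)
  true_th <- vapply(fx$series, `[[`, numeric(1), "thickness_mm")
  expect_lt(max(abs(ana$table$thickness_mm - true_th) / true_th), 0.02)
  # linear MPV decline: 25% at 100% elongation
  tf <- ana$mpv_trend
  expect_gt(tf$r_squared, 0.999)
  expect_equal(tf$slope / tf$intercept, -0.25 / 100, tolerance = 0.01)
  # distribution drift stays modest under calibrated noise
  expect_lt(max(ana$table$bhattacharyya), 0.35)
})
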