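#' Elongation of a stretched skin
#'
#' `Elongation(%) = (L - L0) / L0 * 100`. Compression (`L < L0`) is rejected:
#' the stretch rig only pulls.
#'
#' @param L0_mm Initial length (mm), > 0.
#' @param L_mm Stretched length (mm), >= `L0_mm`.
#' @return Elongation in percent.
#' @examples
#' elongation(50, 60)   # 20
#' elongation(50, 110)  # 120
#' @export
elongation <- function(L0_mm, L_mm) {
  if (L0_mm <= 0) stop("`L0_mm` must be > 0", call. = FALSE)
  if (any(L_mm < L0_mm)) stop("L < L0: compression rejected", call. = FALSE)
  (L_mm - L0_mm) / L0_mm * 100
}

#' Thickness under volume conservation
#'
#' When a skin of initial thickness `t0` stretches so that its detected area
#' grows by `area_ratio`, volume conservation gives the thickness estimate
#' `t0 / area_ratio`. The identity `thickness * area_ratio = t0` holds
#' exactly by construction.
#'
#' @param t0_mm Initial thickness (mm), > 0.
#' @param area_ratio Stretched-to-initial area ratio, >= 1 (a skin under
#'   tension cannot shrink).
#' @return Estimated thickness (mm).
#' @examples
#' thickness_volume_conserved(0.5, 2)  # 0.25
#' @export
thickness_volume_conserved <- function(t0_mm, area_ratio) {
  if (t0_mm <= 0) stop("`t0_mm` must be > 0", call. = FALSE)
  if (any(area_ratio < 1))
    stop("area_ratio < 1: skin cannot shrink under tension", call. = FALSE)
  t0_mm / area_ratio
}

#' Area ratio between two detected regions
#'
#' @param roi0 Reference (unstretched) [roi_mask()].
#' @param roi Stretched [roi_mask()], acquired at the same pixel pitch.
#' @return `roi$area_px / roi0$area_px`.
#' @export
area_ratio_from_rois <- function(roi0, roi) {
  stopifnot(inherits(roi0, "roi_mask"), inherits(roi, "roi_mask"))
  if (roi0$area_px == 0L || roi$area_px == 0L)
    stop("empty mask", call. = FALSE)
  roi$area_px / roi0$area_px
}

#' Mean-removed normalized histogram of ROI pixels
#'
#' Subtracts the ROI mean from the ROI pixels, then histograms the residuals
#' over a common range and normalizes to unit sum. Removing the mean first
#' makes the comparison insensitive to the overall signal decline under
#' stretching, isolating changes in the shape of the distribution. Pairs to
#' be compared must share `range` (and bin count).
#'
#' @param image Numeric matrix or [corrected_image()].
#' @param roi A [roi_mask()] (optional for corrected images).
#' @param n_bins Number of bins (default 256).
#' @param range Length-2 numeric; the common mean-removed range. Defaults to
#'   the range of this image's residuals (fine for single use, but compared
#'   pairs should pass the joint range, see [joint_residual_range()]).
#' @return Numeric vector of `n_bins` probabilities summing to 1, with
#'   attributes `breaks` and `mids`.
#' @export
mean_removed_histogram <- function(image, roi = NULL, n_bins = 256,
                                   range = NULL) {
  if (inherits(image, "corrected_image")) {
    if (is.null(roi)) roi <- image$roi
    image <- image$pixels
  }
  stopifnot(inherits(roi, "roi_mask"))
  if (!any(roi$mask)) stop("empty ROI", call. = FALSE)
  x <- image[roi$mask]
  x <- x - mean(x)
  if (is.null(range)) range <- base::range(x)
  if (diff(range) <= 0) {
    # degenerate spread: all mass in the bin containing 0
    if (stats::sd(x) > 0)
      stop("degenerate range (max = min) for non-constant data",
           call. = FALSE)
    p <- numeric(n_bins)
    p[ceiling(n_bins / 2)] <- 1
    attr(p, "mids") <- rep(0, n_bins)
    return(p)
  }
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  x <- pmin(pmax(x, range[1]), range[2])
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  p <- counts / sum(counts)
  attr(p, "breaks") <- breaks
  attr(p, "mids") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  p
}

#' Joint mean-removed residual range of two ROI images
#'
#' Helper producing the shared histogram range for a compared pair.
#'
#' @param image0,image1 Numeric matrices or [corrected_image()]s.
#' @param roi0,roi1 Matching [roi_mask()]s.
#' @return Length-2 numeric range.
#' @export
joint_residual_range <- function(image0, roi0 = NULL, image1, roi1 = NULL) {
  res <- function(im, roi) {
    if (inherits(im, "corrected_image")) {
      if (is.null(roi)) roi <- im$roi
      im <- im$pixels
    }
    x <- im[roi$mask]
    x - mean(x)
  }
  range(c(res(image0, roi0), res(image1, roi1)))
}

#' Bhattacharyya distance between normalized histograms
#'
#' `D_B = -ln( sum_i sqrt(p_i * q_i) )`. Zero for identical distributions;
#' `+Inf` (flagged) for disjoint supports. With
#' `support = "joint"` the coefficient is computed over bins where both
#' histograms carry mass (each renormalized over that support), which keeps
#' distances finite and interpretable on noisy data; the excluded
#' ("disjoint") mass is reported in the `disjoint_mass` attribute.
#'
#' @param p,q Equal-length non-negative vectors summing to 1 (tolerance
#'   1e-6).
#' @param support `"all"` (textbook definition, default) or `"joint"`.
#' @return The distance, with attribute `disjoint_mass` (max of the mass
#'   either histogram holds where the other is empty).
#' @examples
#' bhattacharyya_distance(c(1, 0), c(0.5, 0.5))  # -log(sqrt(0.5)) ~ 0.3466
#' @export
bhattacharyya_distance <- function(p, q, support = c("all", "joint")) {
  support <- match.arg(support)
  if (length(p) != length(q)) stop("equal bin counts required", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("histograms must be normalized to sum 1", call. = FALSE)
  joint <- p > 0 & q > 0
  disjoint_mass <- max(sum(p[!joint]), sum(q[!joint]))
  if (support == "joint") {
    if (!any(joint)) {
      out <- Inf
      attr(out, "disjoint_mass") <- disjoint_mass
      return(out)
    }
    p <- p[joint] / sum(p[joint])
    q <- q[joint] / sum(q[joint])
  }
  bc <- sum(sqrt(p * q))
  out <- if (bc <= 0) Inf else -log(bc)
  attr(out, "disjoint_mass") <- disjoint_mass
  out
}

#' Linear trend of an image-quality metric against elongation
#'
#' OLS fit of a metric (MPV, SFR50, SFR10, ...) versus elongation in percent,
#' sharing the fit machinery of [fit_stp()]. A metric with zero variance is
#' reported with slope 0 and `r_squared = 0`, flagged via
#' `degenerate_response`.
#'
#' @param elongations_pct Elongations (percent), >= 3 steps.
#' @param metric_values Metric value per step.
#' @return A list of class `trend_fit`: `slope`, `intercept`, `r_squared`,
#'   `max_relative_deviation`, `degenerate_response`, `n`.
#' @export
trend_vs_elongation <- function(elongations_pct, metric_values) {
  if (length(elongations_pct) != length(metric_values))
    stop("length mismatch", call. = FALSE)
  res <- .linear_fit(elongations_pct, metric_values)
  class(res) <- "trend_fit"
  res
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.5g per %%, intercept %.5g, R^2 = %.4f%s\n",
              x$slope, x$intercept, x$r_squared,
              if (x$degenerate_response) " (degenerate response)" else ""))
  invisible(x)
}

#' Partition a region into concentric border zones
#'
#' Divides the detected region into `n_zones` bands by percentile of the
#' distance to the region border (distance transform), zone 1 being the
#' outermost border band. Zones are pairwise disjoint and cover the region
#' exactly; pixel counts per zone are equal up to ties in the discrete
#' distance map (resolved deterministically by scan order).
#'
#' @param roi A [roi_mask()].
#' @param n_zones Number of zones, >= 1.
#' @return List of `n_zones` logical matrices.
#' @export
zone_partition <- function(roi, n_zones) {
  stopifnot(inherits(roi, "roi_mask"))
  n_zones <- as.integer(n_zones)
  if (n_zones < 1L) stop("`n_zones` must be >= 1", call. = FALSE)
  if (n_zones == 1L) return(list(roi$mask))
  if (roi$area_px < n_zones)
    stop("ROI too small for requested zones", call. = FALSE)
  dm <- as.matrix(EBImage::imageData(EBImage::distmap(roi$mask * 1)))
  idx <- which(roi$mask)
  ord <- order(dm[idx], seq_along(idx))  # border-first, deterministic ties
  sizes <- diff(round(seq(0, length(idx), length.out = n_zones + 1)))
  zone_of <- rep(seq_len(n_zones), times = sizes)
  zones <- vector("list", n_zones)
  for (z in seq_len(n_zones)) {
    m <- matrix(FALSE, nrow(roi$mask), ncol(roi$mask))
    m[idx[ord[zone_of == z]]] <- TRUE
    zones[[z]] <- m
  }
  zones
}

#' Full stretch-series analysis
#'
#' Per elongation step: skin detection, dark-corrected MPV, detected area
#' ratio versus the unstretched step, volume-conserved thickness estimate,
#' and Bhattacharyya distance of the mean-removed pixel histogram against
#' step 0 (256 bins over the joint range). Trend fits of MPV versus
#' elongation are returned alongside.
#'
#' @param series Result of [make_stretch_series()] (or an equivalent list of
#'   steps with `elongation_pct` and `stack`, plus dark frames).
#' @param dark_stack A dark [frame_stack()] shared by the series; when `NULL`
#'   a zero dark frame is assumed.
#' @param t0_mm Initial thickness (mm).
#' @param n_bins Histogram bins for the distribution comparison.
#' @return List with `table` (data frame: elongation_pct, mpv, area_ratio,
#'   thickness_mm, bhattacharyya), `mpv_trend` (a `trend_fit`), `rois`.
#' @export
stretch_analysis <- function(series, dark_stack = NULL,
                             t0_mm = attr(series, "t0_mm") %||% 0.5,
                             n_bins = 256) {
  steps <- series
  dark_mean <- if (is.null(dark_stack)) NULL else average_frames(dark_stack)
  per_step <- lapply(steps, function(st) {
    m <- average_frames(st$stack)
    dk <- if (is.null(dark_mean)) {
      matrix(st$scene$response_offset %||% 0, nrow(m), ncol(m))
    } else dark_mean
    sig <- m - dk
    roi <- detect_skin_roi(m, dk,
                           full_scale = st$stack$config$full_scale)
    list(elongation = st$elongation_pct, sig = sig, roi = roi,
         mpv = mean_pixel_value(sig, roi))
  })
  roi0 <- per_step[[1]]$roi
  rows <- lapply(per_step, function(s) {
    ar <- area_ratio_from_rois(roi0, s$roi)
    rng <- joint_residual_range(per_step[[1]]$sig, roi0, s$sig, s$roi)
    p <- mean_removed_histogram(per_step[[1]]$sig, roi0, n_bins, rng)
    q <- mean_removed_histogram(s$sig, s$roi, n_bins, rng)
    data.frame(elongation_pct = s$elongation,
               mpv = s$mpv,
               area_ratio = ar,
               thickness_mm = thickness_volume_conserved(t0_mm, max(ar, 1)),
               bhattacharyya = as.numeric(
                 bhattacharyya_distance(p, q, support = "joint")))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       mpv_trend = trend_vs_elongation(tab$elongation_pct, tab$mpv),
       rois = lapply(per_step, `[[`, "roi"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
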