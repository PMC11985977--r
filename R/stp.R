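#' Air kerma from dosimeter readings
#'
#' The dose metric of the signal-transfer-property analysis: air kerma is the
#' mean of five dose-rate readings (mGy/s) multiplied by the exposure time
#' (s), `A_k = d * t`.
#'
#' @param dose_rates Dose-rate readings in mGy/s; the measurement protocol
#'   takes exactly five.
#' @param exposure_s Exposure time in seconds, > 0.
#' @param allow_any_count Set `TRUE` to accept a reading count other than
#'   five.
#' @return A list of class `dose_measurement` with fields `dose_rates`,
#'   `exposure_s`, `air_kerma` (mGy).
#' @examples
#' air_kerma(rep(2, 5), 0.1)$air_kerma  # 0.2 mGy
#' @export
air_kerma <- function(dose_rates, exposure_s, allow_any_count = FALSE) {
  if (!allow_any_count && length(dose_rates) != 5L)
    stop("exactly five dose-rate readings expected ",
         "(use `allow_any_count = TRUE` to override)", call. = FALSE)
  if (any(dose_rates < 0)) stop("dose rates must be >= 0", call. = FALSE)
  if (exposure_s <= 0) stop("`exposure_s` must be > 0", call. = FALSE)
  structure(list(dose_rates = dose_rates, exposure_s = exposure_s,
                 air_kerma = mean(dose_rates) * exposure_s),
            class = "dose_measurement")
}

#' Mean pixel value over the detected region
#'
#' `MPV = (1/N) * sum of pixel values over the ROI`, with `N` the ROI pixel
#' count. Accepts either a [corrected_image()] (using its own ROI unless one
#' is supplied) or a plain mean frame plus a [roi_mask()].
#'
#' @param image A [corrected_image()] or numeric matrix.
#' @param roi A [roi_mask()]; optional for corrected images.
#' @return The mean pixel value (scalar).
#' @export
mean_pixel_value <- function(image, roi = NULL) {
  if (inherits(image, "corrected_image")) {
    if (is.null(roi)) roi <- image$roi
    image <- image$pixels
  }
  if (is.null(roi)) stop("`roi` is required for plain matrices", call. = FALSE)
  stopifnot(inherits(roi, "roi_mask"), all(dim(image) == dim(roi$mask)))
  if (!any(roi$mask)) stop("empty ROI", call. = FALSE)
  mean(image[roi$mask])
}

# Shared OLS machinery for STP and stretch-trend fits.
.linear_fit <- function(x, y, deviation_tol = 0.02) {
  if (length(x) < 3L) stop("need >= 3 points", call. = FALSE)
  if (diff(range(x)) == 0) stop("degenerate abscissa: all x equal",
                                call. = FALSE)
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  degenerate_y <- isTRUE(all.equal(stats::var(y), 0))
  # R^2 computed directly; summary.lm warns on numerically perfect fits
  r2 <- if (degenerate_y) 0 else
    1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  rel_dev <- abs(y - fitted) / abs(fitted)
  list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
       r_squared = r2, fitted = as.numeric(fitted),
       relative_deviation = as.numeric(rel_dev),
       max_relative_deviation = max(rel_dev),
       is_linear = max(rel_dev) <= deviation_tol,
       degenerate_response = degenerate_y, n = length(x))
}

#' Fit the signal transfer property
#'
#' Ordinary least squares of `MPV = a * A_k + b` over an exposure series,
#' with the coefficient of determination and the per-point relative
#' deviations from the fitted line. The detector counts as linear when no
#' point deviates more than 2% from the model fit (deviation measured
#' against the fitted value).
#'
#' @param points Data frame with columns `air_kerma` (mGy) and `mpv`
#'   (optionally `mpv_sd`), one row per exposure.
#' @param deviation_tol Linearity tolerance on the relative deviation
#'   (default 0.02).
#' @return An object of class `stp_fit` with fields `slope`, `intercept`,
#'   `r_squared`, `max_relative_deviation`, `is_linear`,
#'   `relative_deviation`, `fitted`, `points`.
#' @examples
#' pts <- data.frame(air_kerma = 1:5, mpv = 100 * (1:5) + 7)
#' fit_stp(pts)$r_squared  # 1
#' @export
fit_stp <- function(points, deviation_tol = 0.02) {
  stopifnot(is.data.frame(points),
            all(c("air_kerma", "mpv") %in% names(points)))
  if (length(unique(points$air_kerma)) < 3L)
    stop("need >= 3 points with distinct air kerma", call. = FALSE)
  res <- .linear_fit(points$air_kerma, points$mpv,
                     deviation_tol = deviation_tol)
  res$points <- points
  class(res) <- "stp_fit"
  res
}

#' @export
print.stp_fit <- function(x, ...) {
  cat("<stp_fit>\n")
  cat(sprintf("  MPV = %.6g * A_k + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.7f; max relative deviation = %.3g%% -> %s\n",
              x$r_squared, 100 * x$max_relative_deviation,
              if (x$is_linear) "linear" else "NOT linear"))
  invisible(x)
}

#' Slope table across detector variants
#'
#' Aggregates per-replicate STP slopes for each detector variant (e.g. skin
#' thickness x phosphor ratio x tube voltage): the cell slope is the mean of
#' the replicate slopes and the cell error is their standard deviation across
#' iterations (0 for a single replicate).
#'
#' @param slopes Data frame with one row per replicate fit: grouping columns
#'   plus a `slope` column.
#' @param by Character vector of grouping column names (default: every column
#'   except `slope`).
#' @return Data frame with the grouping columns, `slope` (cell mean),
#'   `slope_error` (std across replicates) and `n_replicates`.
#' @export
stp_slope_table <- function(slopes, by = setdiff(names(slopes), "slope")) {
  stopifnot(is.data.frame(slopes), "slope" %in% names(slopes),
            length(by) >= 1, all(by %in% names(slopes)))
  key <- interaction(slopes[by], drop = TRUE, lex.order = TRUE)
  split_slopes <- split(slopes$slope, key)
  idx <- match(names(split_slopes), as.character(key))
  out <- slopes[idx, by, drop = FALSE]
  out$slope <- vapply(split_slopes, mean, numeric(1))
  out$slope_error <- vapply(split_slopes, function(v)
    if (length(v) > 1L) stats::sd(v) else 0, numeric(1))
  out$n_replicates <- lengths(split_slopes)
  rownames(out) <- NULL
  out
}

#' Run the STP analysis over a simulated or loaded exposure series
#'
#' Convenience chain used by the workflow drivers: averages each stack,
#' detects the skin on the dark-corrected flat, computes the MPV of every
#' dark-corrected exposure over that ROI, and fits the signal transfer
#' property.
#'
#' @param series A series as returned by [make_stp_series()].
#' @param border_margin_px Optional ROI erosion (see [detect_skin_roi()]).
#' @return A list with `points` (data frame of air kerma and MPV), `fit`
#'   (an [fit_stp()] result) and `roi`.
#' @export
stp_analysis <- function(series, border_margin_px = 0) {
  flat_mean <- average_frames(series$flat)
  dark_mean <- average_frames(series$dark)
  roi <- detect_skin_roi(flat_mean, dark_mean,
                         full_scale = series$flat$config$full_scale,
                         border_margin_px = border_margin_px)
  pts <- do.call(rbind, lapply(series$points, function(p) {
    m <- average_frames(p$stack) - dark_mean
    data.frame(air_kerma = p$air_kerma,
               mpv = mean_pixel_value(m, roi))
  }))
  list(points = pts, fit = fit_stp(pts), roi = roi)
}
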