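#' Edge region of interest
#'
#' A sub-image containing exactly one straight, slightly slanted edge, plus
#' the effective pixel pitch. `orientation = "vertical"` means the edge runs
#' roughly along the rows (intensity varies along the columns); horizontal
#' ROIs are transposed internally so that the whole chain works on vertical
#' edges.
#'
#' @param pixels Numeric matrix.
#' @param pitch_mm Effective pixel pitch at the skin plane (mm).
#' @param orientation `"vertical"` or `"horizontal"`.
#' @return An object of class `edge_roi`.
#' @export
edge_roi <- function(pixels, pitch_mm = 0.051,
                     orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(pixels), nrow(pixels) >= 8, ncol(pixels) >= 8,
            pitch_mm > 0)
  structure(list(pixels = pixels, pitch_mm = pitch_mm,
                 orientation = orientation),
            class = "edge_roi")
}

# Matrix with the edge vertical (analysis orientation).
.edge_matrix <- function(roi) {
  if (roi$orientation == "horizontal") t(roi$pixels) else roi$pixels
}

#' Locate the edge with sub-pixel precision
#'
#' For every scan line, the edge position is the centroid of the absolute
#' central-difference derivative of that line, computed in a window around
#' the strongest transition (the windowing keeps the centroid from being
#' dragged toward the line centre by noise far from the edge). A straight
#' line is then fitted to position versus row index; its slope gives the
#' slant angle.
#'
#' @param roi An [edge_roi()].
#' @param window_px Half-width of the centroid window around the derivative
#'   peak of the row-averaged profile (px).
#' @param max_residual_rms Error threshold: fit residual RMS above this (px)
#'   raises "edge not straight".
#' @return List with `positions` (per-row sub-pixel edge columns),
#'   `intercept`, `slope` (px per row), `angle_deg`, `residual_rms`.
#' @export
estimate_edge_line <- function(roi, window_px = 20, max_residual_rms = 1) {
  p <- .edge_matrix(roi)
  nr <- nrow(p); nc <- ncol(p)
  cols <- seq_len(nc)
  rows <- seq_len(nr)
  abs_deriv <- function(line) {
    d <- numeric(nc)
    d[2:(nc - 1)] <- (line[3:nc] - line[1:(nc - 2)]) / 2
    abs(d)
  }
  centroid_at <- function(w, center) {
    lo <- max(2L, round(center) - window_px)
    hi <- min(nc - 1L, round(center) + window_px)
    ww <- w[lo:hi]
    if (sum(ww) == 0) return(NA_real_)
    sum(ww * cols[lo:hi]) / sum(ww)
  }
  # pass 1: window follows each row's own (smoothed) derivative peak
  smooth5 <- function(x) as.numeric(stats::filter(x, rep(0.2, 5),
                                                  sides = 2))
  positions <- rep(NA_real_, nr)
  derivs <- vector("list", nr)
  for (r in rows) {
    w <- abs_deriv(p[r, ])
    derivs[[r]] <- w
    ws <- smooth5(w)
    pk <- which.max(ifelse(is.na(ws), -Inf, ws))
    if (max(w) == 0) next
    positions[r] <- centroid_at(w, pk)
  }
  ok <- is.finite(positions)
  if (sum(ok) < 3L) stop("no detectable edge", call. = FALSE)
  fit <- stats::lm(positions ~ rows, subset = ok)
  # pass 2: recentre every window on the fitted line and refit
  pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * rows
  for (r in rows)
    positions[r] <- centroid_at(derivs[[r]], pred[r])
  ok <- is.finite(positions)
  fit <- stats::lm(positions ~ rows, subset = ok)
  res_rms <- sqrt(mean(stats::residuals(fit)^2))
  if (res_rms > max_residual_rms)
    stop(sprintf("edge not straight (residual RMS %.2f px)", res_rms),
         call. = FALSE)
  slope <- unname(stats::coef(fit)[2])
  list(positions = positions, intercept = unname(stats::coef(fit)[1]),
       slope = slope, angle_deg = atan(slope) * 180 / pi,
       residual_rms = res_rms)
}

#' Validate an edge ROI against the measurement protocol
#'
#' The slanted-edge protocol requires the edge to sit at a small angle (2-7
#' degrees) to the pixel matrix and the ROI to contain dark and bright sides
#' in roughly equal proportion (each side 40-60% of the pixels). Violations
#' are reported, not fatal, so that exploratory measurements can proceed
#' with a warning.
#'
#' @param roi An [edge_roi()].
#' @param angle_range Acceptable absolute slant window in degrees.
#' @param angle_tol Allowance (degrees) added at both window edges for the
#'   uncertainty of the slant estimate itself.
#' @param balance_range Acceptable bright-side fraction.
#' @return List with `angle_deg`, `bright_fraction`, `valid` and a character
#'   vector `reasons` (empty when valid).
#' @export
validate_edge_roi <- function(roi, angle_range = c(2, 7), angle_tol = 0.1,
                              balance_range = c(0.4, 0.6)) {
  line <- estimate_edge_line(roi)
  p <- .edge_matrix(roi)
  lohi <- stats::quantile(p, c(0.05, 0.95), names = FALSE)
  mid <- mean(lohi)
  bright <- mean(p > mid)
  reasons <- character(0)
  a <- abs(line$angle_deg)
  if (a < angle_range[1] - angle_tol || a > angle_range[2] + angle_tol)
    reasons <- c(reasons,
                 sprintf("angle outside %g-%g deg (estimated %.2f deg)",
                         angle_range[1], angle_range[2], line$angle_deg))
  if (bright < balance_range[1] || bright > balance_range[2])
    reasons <- c(reasons,
                 sprintf("side imbalance (bright fraction %.2f)", bright))
  list(angle_deg = line$angle_deg, bright_fraction = bright,
       valid = length(reasons) == 0L, reasons = reasons, line = line)
}

#' Build the oversampled edge-spread function
#'
#' Projects every ROI pixel onto its signed distance from the fitted edge
#' line, bins the distances at `pitch / oversample`, and averages the member
#' pixels per bin. The slant provides the sub-pixel phase diversity that
#' fills the fine bins; empty bins are filled by linear interpolation of
#' their neighbours, and more than 20% empty bins (e.g. an exactly axis
#' aligned edge) aborts with "insufficient slant coverage".
#'
#' @param roi An [edge_roi()].
#' @param edge_line Result of [estimate_edge_line()]; estimated when `NULL`.
#' @param oversample Super-sampling factor (default 4).
#' @return List with `distance_px` (bin centres, in native pixels), `esf`,
#'   `oversample`, `empty_fraction`.
#' @export
build_esf <- function(roi, edge_line = NULL, oversample = 4) {
  p <- .edge_matrix(roi)
  if (is.null(edge_line)) edge_line <- estimate_edge_line(roi)
  nr <- nrow(p); nc <- ncol(p)
  theta <- atan(edge_line$slope)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  d <- ((cc - edge_line$intercept) - edge_line$slope * rr) * cos(theta)
  bin <- floor(d * oversample)
  bins <- seq(min(bin), max(bin))
  sums <- tapply(as.numeric(p), factor(bin, levels = bins), sum)
  counts <- tapply(rep(1, length(bin)), factor(bin, levels = bins), sum)
  counts[is.na(counts)] <- 0
  esf <- as.numeric(sums) / ifelse(counts > 0, counts, NA)
  empty_fraction <- mean(counts == 0)
  if (empty_fraction > 0.2)
    stop("insufficient slant coverage", call. = FALSE)
  centers <- (bins + 0.5) / oversample
  if (any(counts == 0)) {
    filled <- stats::approx(centers[counts > 0], esf[counts > 0],
                            xout = centers, rule = 2)$y
    esf[counts == 0] <- filled[counts == 0]
  }
  list(distance_px = centers, esf = as.numeric(esf), oversample = oversample,
       empty_fraction = empty_fraction)
}

#' Spatial frequency response from an edge-spread function
#'
#' The canonical slanted-edge tail of the chain: the line-spread function is
#' the discrete central-difference derivative of the ESF; a Hamming window
#' centred on the (leftmost) LSF peak suppresses edge noise; the DFT
#' magnitude is corrected for the derivative filter's sinc response,
#' normalized to 1 at zero frequency, converted to lp/mm through
#' `pitch / oversample`, and truncated at the detector Nyquist frequency
#' `1 / (2 * pitch)`.
#'
#' @param esf Result of [build_esf()] (or a plain numeric ESF vector).
#' @param pitch_mm Effective pixel pitch (mm).
#' @param oversample Super-sampling factor of the ESF.
#' @param derivative_correction Divide by the derivative filter's sinc
#'   response (default TRUE).
#' @param window Apodization: `"hamming"` (default) or `"none"`.
#' @param edge_angle_deg Optional slant estimate carried into the result.
#' @return An object of class `sfr_curve` with `frequency_lp_mm`, `value`,
#'   `sfr50`, `sfr10`, `edge_angle_deg`.
#' @export
esf_to_sfr <- function(esf, pitch_mm = 0.051, oversample = 4,
                       derivative_correction = TRUE,
                       window = c("hamming", "none"),
                       edge_angle_deg = NA_real_) {
  window <- match.arg(window)
  if (is.list(esf)) {
    oversample <- esf$oversample
    esf <- esf$esf
  }
  n <- length(esf)
  if (n < 64L) stop("ESF too short (need >= 64 super-samples)", call. = FALSE)
  lsf <- (esf[-(1:2)] - esf[1:(n - 2)]) / 2
  L <- length(lsf)
  peak <- which.max(abs(lsf))[1]
  w <- if (window == "hamming") {
    half <- max(peak - 1L, L - peak)
    0.54 + 0.46 * cos(pi * (seq_len(L) - peak) / half)
  } else rep(1, L)
  mag <- Mod(stats::fft(lsf * w))
  if (mag[1] == 0) stop("zero-frequency magnitude is zero", call. = FALSE)
  nu <- (seq_len(L) - 1) / L                    # cycles per super-sample
  keep <- seq_len(floor(L / 2) + 1L)
  nu <- nu[keep]; mag <- mag[keep]
  if (derivative_correction) {
    corr <- ifelse(nu > 0, sin(2 * pi * nu) / (2 * pi * nu), 1)
    # the correction vanishes at nu = 0.5; guard the far tail
    corr[corr < 0.05] <- 0.05
    mag <- mag / corr
  }
  value <- mag / mag[1]
  freq <- nu * oversample / pitch_mm            # lp/mm
  nyquist <- 1 / (2 * pitch_mm)
  sel <- freq <= nyquist + 1e-12
  curve <- structure(
    list(frequency_lp_mm = freq[sel], value = value[sel],
         nyquist_lp_mm = nyquist, edge_angle_deg = edge_angle_deg,
         pitch_mm = pitch_mm, oversample = oversample),
    class = "sfr_curve")
  s <- sfr_summary(curve)
  curve$sfr50 <- s$sfr50
  curve$sfr10 <- s$sfr10
  curve
}

#' @export
print.sfr_curve <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "beyond Nyquist" else sprintf("%.3f", v)
  cat(sprintf("<sfr_curve> %d frequencies up to Nyquist %.3f lp/mm\n",
              length(x$frequency_lp_mm), x$nyquist_lp_mm))
  cat(sprintf("  SFR50 = %s lp/mm, SFR10 = %s lp/mm\n",
              fmt(x$sfr50), fmt(x$sfr10)))
  invisible(x)
}

#' SFR50 and SFR10 summary frequencies
#'
#' First downward crossings of 0.5 and 0.1, scanning from zero frequency
#' upward with linear interpolation between adjacent grid frequencies.
#' A missing crossing within the measured band is reported as `NA` with the
#' corresponding `beyond_nyquist` flag set ("beyond Nyquist").
#'
#' @param curve An `sfr_curve` (or a list with `frequency_lp_mm`, `value`).
#' @return List with `sfr50`, `sfr10` (lp/mm or `NA`) and logical flags
#'   `sfr50_beyond_nyquist`, `sfr10_beyond_nyquist`.
#' @export
sfr_summary <- function(curve) {
  f <- curve$frequency_lp_mm; v <- curve$value
  cross <- function(level) {
    below <- which(v < level)
    below <- below[below > 1L]
    if (!length(below)) return(NA_real_)
    i <- below[1]
    f[i - 1] + (level - v[i - 1]) * (f[i] - f[i - 1]) / (v[i] - v[i - 1])
  }
  s50 <- cross(0.5); s10 <- cross(0.1)
  list(sfr50 = s50, sfr10 = s10,
       sfr50_beyond_nyquist = is.na(s50), sfr10_beyond_nyquist = is.na(s10))
}

#' Full slanted-edge analysis of an edge ROI
#'
#' Validation, edge-line estimation, ESF construction and SFR computation in
#' one call, the way the workflow drivers use the chain.
#'
#' @param roi An [edge_roi()].
#' @param oversample Super-sampling factor.
#' @param strict When TRUE, protocol violations (slant window, side balance)
#'   abort; otherwise they are attached as warnings to the result.
#' @return An `sfr_curve` with an extra `validation` field.
#' @export
esfr_analysis <- function(roi, oversample = 4, strict = FALSE) {
  val <- validate_edge_roi(roi)
  if (strict && !val$valid)
    stop(paste("edge ROI invalid:", paste(val$reasons, collapse = "; ")),
         call. = FALSE)
  esf <- build_esf(roi, edge_line = val$line, oversample = oversample)
  curve <- esf_to_sfr(esf, pitch_mm = roi$pitch_mm, oversample = oversample,
                      edge_angle_deg = val$angle_deg)
  curve$validation <- val
  curve
}
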