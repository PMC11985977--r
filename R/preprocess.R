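#' Region-of-interest mask for the imaging skin
#'
#' Boolean mask of the detected skin region together with its closed boundary
#' contour and pixel area. Because the skin can move, deform and stretch
#' inside the camera frame, the region is re-detected from a dark-corrected
#' flat acquisition rather than assumed fixed.
#'
#' @param mask Logical matrix, exactly one connected foreground component.
#' @param contour Matrix of ordered boundary pixel coordinates `(row, col)`.
#' @param check Verify single-connectedness (default TRUE).
#' @return An object of class `roi_mask` with fields `mask`, `contour`,
#'   `area_px`.
#' @export
roi_mask <- function(mask, contour = NULL, check = TRUE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  if (check) {
    lab <- EBImage::bwlabel(mask * 1)
    if (max(lab) != 1L)
      stop("ROI mask must have exactly one connected component",
           call. = FALSE)
  }
  if (is.null(contour)) contour <- .mask_contour(mask)
  structure(list(mask = mask, contour = contour, area_px = sum(mask)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px over a %d x %d frame\n",
              x$area_px, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

# Ordered boundary of a single-component mask as (row, col) coordinates.
# EBImage::ocontour treats the first array dimension as x, hence the rename.
.mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))[[1]]
  cbind(row = oc[, 1], col = oc[, 2])
}

#' Detect the imaging-skin region on a dark-corrected flat image
#'
#' The skin appears as one bright region on a dark background in
#' `flat_mean - dark_mean`. Detection is deterministic: Otsu threshold on the
#' dark-corrected flat, 3x3 morphological closing, largest connected
#' component, hole filling, then exclusion of pixels whose flat-dark
#' difference is at or below `eps` (protecting the later flat-field
#' division). The flat should come from the highest-dose condition of the
#' session so that detection happens at maximal contrast.
#'
#' @param flat_mean,dark_mean Mean flat and dark frames (numeric matrices of
#'   equal dimension).
#' @param full_scale Detector full scale, used for the default `eps`.
#' @param eps Pixels with `flat - dark <= eps` are excluded
#'   (default `full_scale * 1e-4`).
#' @param min_area_px Minimum component area; below it detection fails with
#'   "no skin detected".
#' @param border_margin_px Optional erosion of the mask by this many pixels,
#'   for excluding the border zone where optical effects can dominate.
#' @return A [roi_mask()].
#' @export
detect_skin_roi <- function(flat_mean, dark_mean, full_scale = 4095,
                            eps = full_scale * 1e-4, min_area_px = 256,
                            border_margin_px = 0) {
  stopifnot(all(dim(flat_mean) == dim(dark_mean)))
  diffim <- pmax(flat_mean - dark_mean, 0)
  top <- max(diffim)
  if (top <= eps) stop("no skin detected", call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(diffim / top), range = c(0, 1)) * top
  bw <- (diffim > thr) * 1
  bw <- EBImage::closing(bw, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(bw)
  n_comp <- max(lab)
  if (n_comp == 0L) stop("no skin detected", call. = FALSE)
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  if (n_comp > 1L)
    message(sprintf("detect_skin_roi: %d components found, keeping largest",
                    n_comp))
  keep <- which.max(areas)
  bw <- (lab == keep) * 1
  bw <- as.matrix(EBImage::imageData(EBImage::fillHull(bw))) > 0
  if (border_margin_px > 0) {
    er <- EBImage::erode(bw * 1, EBImage::makeBrush(2 * border_margin_px + 1,
                                                    shape = "disc"))
    bw <- as.matrix(EBImage::imageData(er)) > 0
  }
  bw <- bw & (diffim > eps)
  if (sum(bw) < min_area_px) stop("no skin detected", call. = FALSE)
  # eps exclusion may disconnect dead pixels from the bulk; keep the largest
  lab <- EBImage::bwlabel(bw * 1)
  if (max(lab) > 1L) bw <- matrix(lab == which.max(tabulate(lab[lab > 0])),
                                  nrow(bw), ncol(bw))
  roi_mask(bw, check = FALSE)
}

#' Flat-field corrected image
#'
#' Real-valued image defined only inside the detected skin region; pixels
#' outside the region are `NA`, never numeric. `m` is the normalization
#' constant (mean of flat-minus-dark over the region) that restores the
#' corrected image to the original count scale.
#'
#' @param pixels Numeric matrix, `NA` outside the region.
#' @param m Normalization scalar.
#' @param roi The [roi_mask()] the image is defined on.
#' @return An object of class `corrected_image`.
#' @export
corrected_image <- function(pixels, m, roi) {
  stopifnot(inherits(roi, "roi_mask"), all(dim(pixels) == dim(roi$mask)))
  if (any(!is.finite(pixels[roi$mask])))
    stop("non-finite corrected values inside ROI", call. = FALSE)
  structure(list(pixels = pixels, m = m, roi = roi),
            class = "corrected_image")
}

#' @export
print.corrected_image <- function(x, ...) {
  cat(sprintf("<corrected_image> %d x %d px, ROI %d px, m = %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$roi$area_px, x$m))
  invisible(x)
}

#' Flat-field and dark-field correction over the detected region
#'
#' Standard gain/offset correction restricted to the skin region:
#' `corrected = (raw - dark) / (flat - dark) * m`, where `m` is the mean of
#' `flat - dark` inside the region. Correcting the flat stack by itself
#' therefore yields the constant `m`, and a uniform flat with zero dark level
#' leaves the raw image unchanged.
#'
#' @param raw_mean,dark_mean,flat_mean Mean frames of matched dimension.
#' @param roi A [roi_mask()] valid for this acquisition session.
#' @param eps Guard for the denominator; `flat - dark <= eps` inside the ROI
#'   (which detection should have excluded) raises an error.
#' @return A [corrected_image()].
#' @examples
#' raw <- matrix(c(4, 8, 6, 10), 2, 2); flat <- matrix(c(3, 5, 3, 5), 2, 2)
#' roi <- roi_mask(matrix(TRUE, 2, 2))
#' flat_field_correct(raw, matrix(1, 2, 2), flat, roi)$pixels
#' @export
flat_field_correct <- function(raw_mean, dark_mean, flat_mean, roi,
                               eps = 0) {
  stopifnot(inherits(roi, "roi_mask"),
            all(dim(raw_mean) == dim(roi$mask)),
            all(dim(dark_mean) == dim(roi$mask)),
            all(dim(flat_mean) == dim(roi$mask)))
  gain <- flat_mean - dark_mean
  if (any(gain[roi$mask] <= eps))
    stop("flat - dark <= eps inside ROI; re-run detection", call. = FALSE)
  m <- mean(gain[roi$mask])
  out <- matrix(NA_real_, nrow(raw_mean), ncol(raw_mean))
  out[roi$mask] <- (raw_mean[roi$mask] - dark_mean[roi$mask]) /
    gain[roi$mask] * m
  corrected_image(out, m, roi)
}
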