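#' Frame stack container
#'
#' A set of co-registered monochrome frames acquired under one exposure
#' condition, plus acquisition metadata. Frames are stored as real-valued
#' matrices in detector counts (DN); the simulator's idealized ADC does not
#' quantize, so noiseless stacks carry exact expected values.
#'
#' @param frames List of numeric matrices of identical dimension.
#' @param config A [detector_config()].
#' @param label One of `"raw"`, `"flat"`, `"dark"`.
#' @param air_kerma Air kerma of the acquisition (mGy), if known.
#' @param meta Optional list of extra metadata (scene parameters, seed, ...).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, config, label = c("raw", "flat", "dark"),
                        air_kerma = NA_real_, meta = list()) {
  label <- match.arg(label)
  if (!length(frames)) stop("empty frame stack", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("frames differ in dimension", call. = FALSE)
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > config$full_scale)
    stop("pixel values outside [0, full_scale]", call. = FALSE)
  structure(list(frames = frames, config = config, label = label,
                 air_kerma = air_kerma, meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d x %d px, %d frame(s), label '%s'",
              d[1], d[2], length(x$frames), x$label))
  if (!is.na(x$air_kerma)) cat(sprintf(", air kerma %.4g mGy", x$air_kerma))
  cat("\n")
  invisible(x)
}

#' Average the frames of a stack
#'
#' Per-pixel arithmetic mean over all frames, kept real-valued (no integer
#' truncation). Averaging n independent frames reduces per-pixel noise by
#' about sqrt(n), which is the reason the rig buffers and averages 10 frames
#' per acquisition.
#'
#' @param stack A [frame_stack()] (or a plain list of matrices).
#' @return A numeric matrix, the mean frame.
#' @examples
#' cfg <- detector_config(n_frames = 2)
#' st <- frame_stack(list(matrix(10, 2, 2), matrix(20, 2, 2)), cfg)
#' average_frames(st)  # all pixels 15
#' @export
average_frames <- function(stack) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (!length(frames)) stop("empty frame stack", call. = FALSE)
  Reduce(`+`, frames) / length(frames)
}

#' Write a frame stack as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pixel values are stored as 16-bit samples scaled by the container maximum
#' (65535); the sidecar records the detector configuration, label, air kerma
#' and any simulation metadata needed to reinterpret the stack.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  container_max <- 2^stack$config$bit_depth - 1
  pages <- lapply(stack$frames, function(f) round(f) / container_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(
    label = stack$label,
    air_kerma_mGy = stack$air_kerma,
    n_frames = length(stack$frames),
    shape_px = dim(stack$frames[[1]]),
    config = unclass(stack$config),
    meta = stack$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path with a `<path>.json` sidecar next to it.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(detector_config, sidecar$config)
  container_max <- 2^cfg$bit_depth - 1
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) round(p * container_max))
  frame_stack(frames, cfg, label = sidecar$label,
              air_kerma = if (is.null(sidecar$air_kerma_mGy)) NA_real_
                          else sidecar$air_kerma_mGy,
              meta = if (is.null(sidecar$meta)) list() else sidecar$meta)
}
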