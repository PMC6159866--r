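# Calibrated grayscale raster container and TIFF/PNG input/output.
# Pixels are stored as a numeric matrix in [0, 1], row-major with the origin
# at the top-left (matrix row 1 = top image row); pixels are square and
# pixel_size_um gives the physical edge length of one pixel.

#' Calibrated grayscale micrograph
#'
#' @param pixels Numeric matrix of intensities. Integer-valued 8/16-bit data
#'   are rescaled to \[0, 1\]; real-valued input must already lie in \[0, 1\].
#' @param pixel_size_um Physical size of one (square) pixel in micrometres.
#' @return An object of class `grayscale_image`.
#' @export
grayscale_image <- function(pixels, pixel_size_um) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), length(pixels) > 0,
            all(is.finite(pixels)),
            is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            is.finite(pixel_size_um), pixel_size_um > 0)
  mx <- max(pixels)
  if (mx > 1) {
    # integer-coded data: pick the smallest standard bit depth that fits
    depth <- if (mx <= 255) 255 else if (mx <= 65535) 65535 else mx
    pixels <- pixels / depth
  }
  if (min(pixels) < 0) stop("negative intensities are not supported")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "grayscale_image")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("grayscale image: %d x %d px, %.4g um/px (%.3g x %.3g um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um,
              ncol(x$pixels) * x$pixel_size_um))
  invisible(x)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Multi-channel rasters are collapsed to grayscale by channel averaging.
#' The physical pixel size is not stored in these formats reliably, so it is
#' supplied by the caller (typically from a manifest CSV).
#'
#' @param path File path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param pixel_size_um Micrometres per pixel.
#' @return A [grayscale_image()].
#' @export
read_grayscale_image <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image extension '%s' (need tif/tiff/png)", ext)))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  grayscale_image(arr, pixel_size_um)
}

#' Write a grayscale micrograph to TIFF or PNG
#'
#' @param image A [grayscale_image()].
#' @param path Output path; `.tif`/`.tiff` writes 16-bit TIFF (matching SEM
#'   dynamic range), `.png` writes 16-bit PNG.
#' @return `path`, invisibly.
#' @export
write_grayscale_image <- function(image, path) {
  stopifnot(inherits(image, "grayscale_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop(sprintf("unsupported image extension '%s' (need tif/tiff/png)", ext)))
  invisible(path)
}

#' One-dimensional surface height profile
#'
#' Heights (micrometres, measured upward from the bottom image edge) sampled
#' at uniform horizontal spacing `dx_um`.
#'
#' @param heights Numeric vector of heights, length >= 2, finite.
#' @param dx_um Horizontal sample spacing in micrometres.
#' @return An object of class `surface_profile`.
#' @export
surface_profile <- function(heights, dx_um) {
  stopifnot(is.numeric(heights), length(heights) >= 2L,
            all(is.finite(heights)),
            is.numeric(dx_um), length(dx_um) == 1L, dx_um > 0)
  structure(list(heights = as.numeric(heights), dx_um = dx_um),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("surface profile: %d samples, dx %.4g um, span %.3g um, height range [%.3g, %.3g] um\n",
              length(x$heights), x$dx_um,
              (length(x$heights) - 1) * x$dx_um,
              min(x$heights), max(x$heights)))
  invisible(x)
}
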