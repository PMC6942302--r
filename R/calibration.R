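#' Hounsfield calibration range
#'
#' The fixed window used to map raw CT attenuation values (Hounsfield units,
#' HU; air = -1000, water = 0) onto the 8-bit working range. The default
#' window \eqn{[-1000, 9240]} is wide enough to cover the attenuation of all
#' plant tissues, so values outside it are treated as saturations and
#' clamped, not rejected.
#'
#' @param hu_min,hu_max window endpoints in HU; `hu_min < hu_max`.
#' @return an object of class `calibration_range`.
#' @export
#' @examples
#' calibration_range()
calibration_range <- function(hu_min = -1000, hu_max = 9240) {
  stopifnot(is.numeric(hu_min), is.numeric(hu_max),
            length(hu_min) == 1L, length(hu_max) == 1L,
            is.finite(hu_min), is.finite(hu_max))
  if (hu_min >= hu_max)
    stop("degenerate calibration range: hu_min must be strictly below hu_max")
  structure(list(hu_min = hu_min, hu_max = hu_max),
            class = "calibration_range")
}

#' @export
print.calibration_range <- function(x, ...) {
  cat(sprintf("<calibration_range> [%g, %g] HU -> [0, 255]\n",
              x$hu_min, x$hu_max))
  invisible(x)
}

# round-half-away-from-zero; inputs here are always >= 0
.round_half_up <- function(x) floor(x + 0.5)

#' 8-bit grey-level cross-section image with physical scale
#'
#' @param pixels integer-valued matrix with grey levels in `[0, 255]`,
#'   indexed `[row, col]`.
#' @param pixel_size_mm physical edge length of one pixel in mm
#'   (default 0.01355, i.e. 13.55 micrometre micro-CT resolution).
#' @param source_id free-text provenance tag.
#' @return an object of class `slice_image`.
#' @export
slice_image <- function(pixels, pixel_size_mm = 0.01355, source_id = "") {
  stopifnot(is.matrix(pixels), is.numeric(pixel_size_mm),
            length(pixel_size_mm) == 1L)
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("grey levels must be finite and within [0, 255]")
  structure(list(pixels = px, pixel_size_mm = pixel_size_mm,
                 source_id = as.character(source_id)),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d px, %.5f mm/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
dim.slice_image <- function(x) dim(x$pixels)

#' Convert raw HU values to an 8-bit grey-level slice
#'
#' Values are clamped to the calibration window and scaled linearly so that
#' `hu_min` maps to grey 0 and `hu_max` to grey 255; the result is rounded
#' to the nearest integer (ties away from zero). The mapping is monotone
#' non-decreasing in HU.
#'
#' @param raw numeric matrix of HU values (finite).
#' @param cal a [calibration_range()].
#' @param pixel_size_mm,source_id forwarded to [slice_image()].
#' @return a [slice_image()].
#' @export
#' @examples
#' hu_to_gray(matrix(c(-1000, 0, 9240), 1), calibration_range())$pixels
hu_to_gray <- function(raw, cal = calibration_range(),
                       pixel_size_mm = 0.01355, source_id = "") {
  stopifnot(is.matrix(raw), inherits(cal, "calibration_range"))
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("raw HU values must be finite")
  clamped <- pmin(pmax(raw, cal$hu_min), cal$hu_max)
  grey <- .round_half_up(255 * (clamped - cal$hu_min) /
                           (cal$hu_max - cal$hu_min))
  slice_image(matrix(grey, nrow(raw), ncol(raw)),
              pixel_size_mm = pixel_size_mm, source_id = source_id)
}

#' Load a cross-section image from disk
#'
#' Single-channel 8-bit TIFF/PNG images pass through unchanged; 16-bit TIFF
#' input is interpreted as HU values (one code = one HU) and requires a
#' calibration range.
#'
#' @param path image file (`.tif`/`.tiff`/`.png`).
#' @param pixel_size_mm physical pixel size in mm.
#' @param cal a [calibration_range()], required for 16-bit input.
#' @return a [slice_image()].
#' @export
load_slice <- function(path, pixel_size_mm = 0.01355, cal = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    raw <- round(raw * 255)
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] == 1L) raw <- raw[, , 1L]
    else stop("multi-channel input is not supported (single-channel expected)")
  }
  if (max(raw) > 255) {                     # 16-bit codes, treated as HU
    if (is.null(cal))
      stop("16-bit input requires a calibration range")
    hu_to_gray(raw, cal, pixel_size_mm = pixel_size_mm,
               source_id = basename(path))
  } else {
    slice_image(raw, pixel_size_mm = pixel_size_mm,
                source_id = basename(path))
  }
}

#' Write a slice image to disk
#'
#' 8-bit single-channel TIFF or PNG, chosen by file extension. A written
#' slice re-loads bit-identically through [load_slice()].
#'
#' @param img a [slice_image()].
#' @param path destination path (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_slice <- function(img, path) {
  stopifnot(inherits(img, "slice_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}
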