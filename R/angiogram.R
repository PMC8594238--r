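#' En-face angiogram image
#'
#' Container for a 2D grayscale en-face OCTA flow image.  Pixels are gray
#' levels in 0--255 (stored as a numeric matrix), with physical pixel
#' spacing in mm/pixel and a modality tag.
#'
#' @param pixels numeric matrix of gray levels in `[0, 255]`
#' @param pixel_spacing physical pixel spacing in mm/pixel
#' @param modality `"iris"` (3 x 3 mm anterior-segment scan) or `"macula"`
#'   (6 x 6 mm macular scan)
#' @param eye laterality tag: `"OD"`, `"OS"` or `"unspecified"`.  Carried
#'   as metadata; it does not alter any geometry.
#' @return An object of class `angiogram`.
#' @examples
#' img <- angiogram(matrix(80, 64, 64), pixel_spacing = 3 / 64)
#' dim(img$pixels)
#' @export
angiogram <- function(pixels, pixel_spacing,
                      modality = c("iris", "macula"),
                      eye = c("unspecified", "OD", "OS")) {
  modality <- match.arg(modality)
  eye <- match.arg(eye)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive number (mm/pixel)",
         call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel gray levels must lie in [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         modality = modality, eye = eye),
    class = "angiogram"
  )
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("<angiogram> %d x %d px, %s, %.4f mm/px, eye %s\n",
              nrow(x$pixels), ncol(x$pixels), x$modality,
              x$pixel_spacing, x$eye))
  cat(sprintf("  gray levels: %.0f..%.0f\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an angiogram from a PNG or TIFF file
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF image and wraps it as an
#' [angiogram()].  Multichannel images are reduced to their first channel.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file
#' @param pixel_spacing mm/pixel; by default derived from the modality's
#'   scan width (3 mm iris / 6 mm macula) divided by the image width
#' @inheritParams angiogram
#' @return An [angiogram()].
#' @export
read_angiogram <- function(path, modality = c("iris", "macula"),
                           pixel_spacing = NULL,
                           eye = c("unspecified", "OD", "OS")) {
  modality <- match.arg(modality)
  eye <- match.arg(eye)
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  px <- round(arr * 255)
  if (is.null(pixel_spacing)) {
    scan_mm <- if (modality == "iris") 3 else 6
    pixel_spacing <- scan_mm / ncol(px)
  }
  angiogram(px, pixel_spacing, modality, eye)
}

#' Write an angiogram (or binary mask) as an 8-bit grayscale image
#'
#' @param x an [angiogram()], or a matrix: gray levels in `[0, 255]`, or a
#'   binary 0/1 matrix (written as black/white)
#' @param path output path ending in `.png`, `.tif` or `.tiff`
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(x, path) {
  px <- if (inherits(x, "angiogram")) x$pixels else x
  if (!is.matrix(px)) stop("`x` must be an angiogram or a matrix",
                           call. = FALSE)
  if (all(px %in% c(0, 1))) px <- px * 255
  m <- px / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  invisible(path)
}
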