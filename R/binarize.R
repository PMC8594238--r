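#' Binarization configuration
#'
#' Settings for [binarize_angiogram()].  The default is a parameter-free
#' global Otsu threshold, the usual choice for OCTA en-face
#' quantification; a local adaptive mean-minus-offset rule is available
#' as an alternative.  An optional white top-hat transform flattens slow
#' background variation before thresholding.  `threshold_jitter_sd`
#' perturbs the threshold by a zero-mean Gaussian (gray levels) and
#' exists to emulate operator re-measurement variability across
#' replicates; the default 0 keeps binarization fully deterministic.
#'
#' @param method `"otsu"` (global) or `"adaptive"` (local mean plus
#'   `adaptive_offset` over an `adaptive_window` square neighborhood)
#' @param tophat_radius radius (px) of the disc structuring element for
#'   white top-hat background flattening; 0 disables it
#' @param adaptive_window odd window side (px) for the adaptive method
#' @param adaptive_offset gray-level offset added to the local mean: a
#'   pixel is vessel when it exceeds its local mean by more than this
#'   margin (keeps flat regions in the background)
#' @param min_object_px connected components (8-connectivity) smaller than
#'   this are removed before skeletonization; suppresses speckle-induced
#'   skeleton fragments
#' @param threshold_jitter_sd SD (gray levels) of the threshold jitter
#' @return An object of class `binarize_config`.
#' @export
binarize_config <- function(method = c("otsu", "adaptive"),
                            tophat_radius = 0,
                            adaptive_window = 31L,
                            adaptive_offset = 10,
                            min_object_px = 4L,
                            threshold_jitter_sd = 0) {
  method <- match.arg(method)
  if (adaptive_window %% 2L == 0L)
    stop("`adaptive_window` must be odd", call. = FALSE)
  structure(
    list(method = method, tophat_radius = tophat_radius,
         adaptive_window = as.integer(adaptive_window),
         adaptive_offset = adaptive_offset,
         min_object_px = as.integer(min_object_px),
         threshold_jitter_sd = threshold_jitter_sd),
    class = "binarize_config"
  )
}

#' Binarize an angiogram into a vessel mask
#'
#' Thresholds the flow image into vessel (1) and background (0).  With
#' the default Otsu method the threshold is estimated from the gray-level
#' histogram of `roi` (when given) or of the whole frame, then applied to
#' the whole frame; passing the measurement window as `roi` keeps the
#' pupil and sclera gray levels out of the histogram.  The output is
#' deterministic given the image and configuration (threshold jitter, if
#' enabled, is driven by `jitter_seed`).
#'
#' @param image an [angiogram()] or a numeric matrix of gray levels
#' @param config a [binarize_config()]
#' @param roi optional [roi_spec()] over which to estimate the threshold
#' @param jitter_seed seed used only when `threshold_jitter_sd > 0`
#' @return A 0/1 integer matrix of the same shape, with attributes
#'   `provenance = "thresholded"` and `threshold` (the gray level used;
#'   `NA` for the adaptive method).
#' @examples
#' px <- matrix(50, 40, 40); px[10:12, ] <- 200
#' m <- binarize_angiogram(px)
#' sum(m) == 3 * 40
#' @export
binarize_angiogram <- function(image, config = binarize_config(),
                               roi = NULL, jitter_seed = NULL) {
  px <- if (inherits(image, "angiogram")) image$pixels else image
  if (!is.matrix(px)) stop("`image` must be an angiogram or a matrix",
                           call. = FALSE)
  if (config$tophat_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(config$tophat_radius) + 1L,
                                shape = "disc")
    px <- EBImage::whiteTopHat(px / 255, brush) * 255
  }
  region <- if (is.null(roi)) px else px[roi_rows(roi), roi_cols(roi)]
  if (max(region) - min(region) < .Machine$double.eps * 255) {
    warning("constant-intensity image: no threshold separates vessel ",
            "from background; returning an all-background mask",
            call. = FALSE)
    mask <- matrix(0L, nrow(px), ncol(px))
    attr(mask, "provenance") <- "thresholded"
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  if (config$method == "otsu") {
    th <- EBImage::otsu(region / 255, range = c(0, 1), levels = 256L) * 255
    if (config$threshold_jitter_sd > 0) {
      th <- th + with_seed(jitter_seed,
                           rnorm(1, 0, config$threshold_jitter_sd))
    }
    mask <- px > th
  } else {
    w <- config$adaptive_window
    kern <- matrix(1 / (w * w), w, w)
    local_mean <- EBImage::filter2(px, kern)
    mask <- px > local_mean + config$adaptive_offset
    th <- NA_real_
  }
  mask <- matrix(as.integer(mask), nrow(px), ncol(px))
  attr(mask, "provenance") <- "thresholded"
  attr(mask, "threshold") <- as.numeric(th)
  mask
}

#' Label 8-connected components of a binary mask
#'
#' @param mask 0/1 matrix
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  .label_cpp(binary_matrix(mask))
}

#' Remove small connected components ("specks") from a binary mask
#'
#' @param mask 0/1 matrix
#' @param min_size components (8-connectivity) with fewer pixels than
#'   this are removed
#' @return 0/1 integer matrix.
#' @export
remove_small_objects <- function(mask, min_size = 4L) {
  m <- binary_matrix(mask)
  if (min_size <= 1L || sum(m) == 0L) return(m)
  lab <- .label_cpp(m)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_size)
  if (length(drop)) m[lab %in% drop] <- 0L
  m
}

# Coerce to a validated 0/1 integer matrix.
binary_matrix <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stop("`mask` must be a binary (0/1) matrix", call. = FALSE)
  matrix(as.integer(mask), nrow(mask), ncol(mask))
}
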