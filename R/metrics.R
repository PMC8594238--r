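#' Vessel area density (VAD) over a region of interest
#'
#' VAD is the ratio of the area occupied by (binarized) vessels to the
#' total area of the region: vessel pixel count inside the ROI divided by
#' the ROI pixel area.
#'
#' @param mask 0/1 vessel mask
#' @param roi an [roi_spec()]; must lie within the mask bounds
#' @return A fraction in `[0, 1]`.
#' @examples
#' m <- matrix(0L, 10, 10); m[1:5, 1:5] <- 1L
#' compute_vad(m, roi_spec(0, 10, 0, 10))  # 0.25
#' @export
compute_vad <- function(mask, roi) {
  m <- binary_matrix(mask)
  check_roi_bounds(roi, dim(m))
  sum(m[roi_rows(roi), roi_cols(roi)]) / roi_area(roi)
}

#' Vessel skeleton density (VSD) over a region of interest
#'
#' VSD is the ratio of the length occupied by vessels to the total area
#' of the region: skeleton pixel count inside the ROI divided by the ROI
#' pixel area.  By default length is the plain pixel count of the
#' one-pixel-wide centerline (the pixel-ratio convention of OMAG-style
#' VSD); `diagonal_corrected = TRUE` instead sums link lengths along the
#' skeleton (1 per horizontal/vertical link, sqrt(2) per diagonal link,
#' isolated pixels counting 1).
#'
#' Because the skeleton is a subset of its parent mask, VSD never exceeds
#' the VAD of that mask over the same ROI.
#'
#' @param skeleton 0/1 skeleton map (see [skeletonize_mask()])
#' @param roi an [roi_spec()]
#' @param diagonal_corrected use geodesic link lengths instead of the
#'   pixel count
#' @return A fraction in `[0, 1]`.
#' @export
compute_vsd <- function(skeleton, roi, diagonal_corrected = FALSE) {
  s <- binary_matrix(skeleton)
  check_roi_bounds(roi, dim(s))
  sub <- s[roi_rows(roi), roi_cols(roi), drop = FALSE]
  if (!diagonal_corrected) return(sum(sub) / roi_area(roi))
  # half the summed link lengths over both directions of each link
  H <- nrow(sub); W <- ncol(sub)
  orth <- sum(sub[-H, ] * sub[-1, ]) + sum(sub[, -W] * sub[, -1])
  diag1 <- sum(sub[-H, -W] * sub[-1, -1]) + sum(sub[-H, -1] * sub[-1, -W])
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- sub
  nb <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + p[(2:(H + 1)) + dr, (2:(W + 1)) + dc]
  }
  n_iso <- sum(sub == 1L & nb == 0L)
  len <- orth + sqrt(2) * diag1 + n_iso
  len / roi_area(roi)
}

check_roi_bounds <- function(roi, dims) {
  if (!inherits(roi, "roi_spec"))
    stop("`roi` must be an roi_spec", call. = FALSE)
  if (roi_area(roi) <= 0L)
    stop("empty ROI (zero area)", call. = FALSE)
  if (roi$row_max > dims[1] || roi$col_max > dims[2])
    stop("ROI exceeds image bounds (rows/cols up to ",
         dims[1], "/", dims[2], ")", call. = FALSE)
  invisible(roi)
}

#' Measure VAD and VSD for one eye, per segment, with replicates
#'
#' Runs the full quantification chain — binarize, remove specks,
#' skeletonize, compute VAD/VSD per segment — `n_replicates` times and
#' averages, mirroring the practice of measuring each value three times
#' and taking the mean.  With the default deterministic binarization all
#' replicates are identical and the mean equals a single pass; setting
#' `threshold_jitter_sd > 0` in `binarize_config` emulates operator
#' re-measurement variability, with replicate thresholds drawn from
#' seeded substreams of `seed` so results are bit-reproducible.
#'
#' For iris images the segments are the nested `one_third`, `two_thirds`
#' and `full` pupil-margin windows; for macula images a single
#' `retina_full` window covering the frame.
#'
#' @param image an [angiogram()]
#' @param landmarks an [iris_landmarks()]; required for iris images
#'   (see [locate_landmarks()] for automatic detection)
#' @param n_replicates number of measurement repeats (default 3)
#' @param config a [binarize_config()]
#' @param half_height,span,mode ROI parameters, see [build_iris_rois()]
#' @param seed master seed for jittered replicates
#' @return An object of class `perfusion_metrics`: a list with
#'   `summary` (data.frame: segment, vad, vsd — replicate means) and
#'   `replicates` (data.frame: segment, replicate, vad, vsd).
#' @export
measure_eye <- function(image, landmarks = NULL, n_replicates = 3L,
                        config = binarize_config(),
                        half_height = 150, span = 150,
                        mode = "nested", seed = 1L) {
  if (!inherits(image, "angiogram"))
    stop("`image` must be an angiogram", call. = FALSE)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  dims <- dim(image$pixels)
  if (image$modality == "iris") {
    if (is.null(landmarks))
      stop("iris measurement requires landmarks (see locate_landmarks())",
           call. = FALSE)
    pts <- rbind(landmarks$pupil_center, landmarks$pupil_margin,
                 landmarks$limbus)
    if (any(pts[, 1] < 0 | pts[, 1] > dims[1] - 1 |
            pts[, 2] < 0 | pts[, 2] > dims[2] - 1))
      stop("landmarks lie outside the image", call. = FALSE)
    rois <- build_iris_rois(landmarks, half_height = half_height,
                            span = span, mode = mode, image_dim = dims)
  } else {
    rois <- list(retina_full = build_macula_roi(image))
  }
  est_roi <- rois[[length(rois)]]  # full window drives the threshold

  reps <- lapply(seq_len(n_replicates), function(k) {
    mask <- binarize_angiogram(image, config, roi = est_roi,
                               jitter_seed = substream_seed(seed, k))
    mask <- remove_small_objects(mask, config$min_object_px)
    skel <- skeletonize_mask(mask)
    do.call(rbind, lapply(names(rois), function(nm) {
      data.frame(segment = nm, replicate = k,
                 vad = compute_vad(mask, rois[[nm]]),
                 vsd = compute_vsd(skel, rois[[nm]]),
                 stringsAsFactors = FALSE)
    }))
  })
  replicates <- do.call(rbind, reps)
  summary <- stats::aggregate(cbind(vad, vsd) ~ segment, replicates, mean)
  summary <- summary[match(names(rois), summary$segment), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, replicates = replicates,
                 n_replicates = as.integer(n_replicates)),
            class = "perfusion_metrics")
}

#' @export
print.perfusion_metrics <- function(x, ...) {
  cat(sprintf("<perfusion_metrics> %d replicate(s)\n", x$n_replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
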