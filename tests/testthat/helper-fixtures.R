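# Shared fixtures, generated in code.

# A compact iris phantom configuration for fast tests; geometry scaled
# down from the package defaults, used with half_height = 80, span = 90.
small_iris_config <- function(seed = 1L, ...) {
  base <- list(image_height = 240L, image_width = 240L,
               pupil_center = c(120, 190), pupil_radius = 45,
               limbus_offset = 25, n_vessels = 70L,
               vessel_width_range = c(1L, 3L), seed = seed)
  do.call(phantom_config, utils::modifyList(base, list(...)))
}

small_roi_args <- list(half_height = 80, span = 90)

small_rois <- function(landmarks, dims, mode = "nested") {
  build_iris_rois(landmarks, half_height = small_roi_args$half_height,
                  span = small_roi_args$span, mode = mode,
                  image_dim = dims)
}

# Two-level image (no noise): vessels at `fg` on background `bg`.
two_level_phantom <- function(seed = 1L, fg = 200, bg = 50) {
  cfg <- small_iris_config(seed = seed, speckle_sd = 0,
                           vessel_intensity = fg,
                           background_intensity = bg)
  generate_iris_phantom(cfg)
}

# Random small binary shapes for morphology property tests.
random_blob_mask <- function(seed, n = 80L, dims = c(90L, 90L)) {
  set.seed(seed)
  m <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(n)) {
    r <- sample.int(dims[1] - 6L, 1L); c <- sample.int(dims[2] - 6L, 1L)
    h <- sample.int(6L, 1L); w <- sample.int(6L, 1L)
    m[r:(r + h), c:(c + w)] <- 1L
  }
  m
}

count_components <- function(mask) {
  lab <- label_components(mask)
  max(lab)
}

neighbor_counts <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- mask
  nb <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + p[(2:(H + 1)) + dr, (2:(W + 1)) + dc]
  }
  nb
}
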