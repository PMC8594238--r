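#' Skeletonize a vessel mask
#'
#' Reduces a binary vessel mask to its one-pixel-wide centerline by
#' border-sequential topology-preserving thinning: in each iteration four
#' directional passes (north, south, west, east) delete boundary pixels
#' that are simple points — pixels whose removal leaves the local
#' foreground topology unchanged, characterized by a Yokoi 8-connectivity
#' number of 1 — while line endpoints (pixels with exactly one neighbor)
#' are never deleted, so centerlines keep their full length up to end
#' effects.  The border set of each pass is frozen at its start, so at
#' most one pixel layer is peeled per pass.
#'
#' The result satisfies, by construction: skeleton is a subset of the
#' mask; 8-connected components are preserved; re-skeletonizing changes
#' nothing (idempotence).
#'
#' @param mask 0/1 matrix (vessel mask)
#' @return 0/1 integer matrix of the skeleton.
#' @examples
#' bar <- matrix(0L, 9, 104); bar[3:7, 3:102] <- 1L
#' sum(skeletonize_mask(bar))  # ~100: the bar's midline
#' @export
skeletonize_mask <- function(mask) {
  .thin_cpp(binary_matrix(mask))
}
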